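# Synthetic polypeptide fixtures: ideal secondary-structure backbones built
# from standard internal coordinates, controlled-identity homologues, hinge
# conformers and complete benchmark cases. Side chains stop at CB so every
# generated atom participates in the backbone/CB computations downstream.

# ideal bond lengths (A) and angles (deg) for a trans peptide
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, dih_cb = -122.6, omega = 180)

# phi/psi for canonical secondary structures
SS_PHIPSI <- list(helix = c(-57, -47), strand = c(-139, 135))

build_backbone <- function(phi, psi, resid = "ALA", chain = "A", id = "model",
                           resno_start = 1L) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  resid <- rep_len(resid, n)
  g <- BB_GEOM
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  a <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$c_n, g$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, psi[i] + 180)
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ],
                          g$ca_cb, g$ang_n_ca_cb, g$dih_cb)
  }
  per_res <- function(i) {
    names <- c("N", "CA", "C", "O", "CB")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], CB[i, ])
    data.frame(type = "ATOM", chain = chain,
               resno = resno_start + i - 1L, ins = "", resid = resid[i],
               elety = names, elesy = substr(names, 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               o = 1, b = 0, polymer = TRUE, stringsAsFactors = FALSE)
  }
  new_structure(do.call(rbind, lapply(seq_len(n), per_res)), id = id)
}

#' Generate an ideal poly-alanine alpha-helix
#'
#' Backbone built from standard internal coordinates at canonical helical
#' torsions (phi -57, psi -47 degrees), giving a rise of ~1.5 A and ~100
#' degrees of twist per residue, with atoms N, CA, C, O and CB per residue.
#'
#' @param n Number of residues (>= 1).
#' @param chain Chain identifier.
#' @param id Structure label.
#' @return A \code{"pdb_structure"} with \code{5 * n} atoms.
#' @examples
#' h <- make_ideal_helix(12)
#' nrow(h$atoms)  # 60
#' @export
make_ideal_helix <- function(n, chain = "A", id = "helix") {
  if (!is.numeric(n) || n < 1)
    stop_lrr("input_error", "helix length must be >= 1 residue")
  pp <- SS_PHIPSI$helix
  build_backbone(rep(pp[1], n), rep(pp[2], n), chain = chain, id = id)
}

#' Generate an ideal extended beta-strand
#'
#' @inheritParams make_ideal_helix
#' @return A \code{"pdb_structure"} with \code{5 * n} atoms.
#' @export
make_ideal_strand <- function(n, chain = "A", id = "strand") {
  if (!is.numeric(n) || n < 1)
    stop_lrr("input_error", "strand length must be >= 1 residue")
  pp <- SS_PHIPSI$strand
  build_backbone(rep(pp[1], n), rep(pp[2], n), chain = chain, id = id)
}

#' Generate a mixed helix-strand chain
#'
#' First \code{n_helix} residues at helical torsions, remainder extended;
#' used as a generic single-domain fold for benchmark cases.
#'
#' @param n_helix,n_strand Residue counts of the two segments.
#' @inheritParams make_ideal_helix
#' @return A \code{"pdb_structure"}.
#' @export
make_mixed_chain <- function(n_helix, n_strand, chain = "A", id = "mixed") {
  if (n_helix < 1 || n_strand < 0)
    stop_lrr("input_error", "invalid segment lengths")
  phi <- c(rep(SS_PHIPSI$helix[1], n_helix), rep(SS_PHIPSI$strand[1], n_strand))
  psi <- c(rep(SS_PHIPSI$helix[2], n_helix), rep(SS_PHIPSI$strand[2], n_strand))
  build_backbone(phi, psi, chain = chain, id = id)
}

#' Generate a two-stranded antiparallel beta-sheet
#'
#' Chain A is an ideal extended strand; chain B is its copy rotated 180
#' degrees about the axis normal to the strand through its centroid and
#' offset so the backbone amides of the two strands face each other in
#' hydrogen-bonding register (offsets calibrated for the default strand
#' length of 6 residues; other lengths form partial ladders).
#'
#' @param n Residues per strand.
#' @param id Structure label.
#' @return A \code{"pdb_structure"} with chains A and B.
#' @export
make_antiparallel_sheet <- function(n = 6, id = "sheet") {
  s1 <- make_ideal_strand(n, chain = "A", id = id)
  at <- s1$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  R <- rotation_matrix(c(0, 0, 1), 180)
  xyz2 <- sweep(xyz, 2, ctr) %*% t(R) +
    matrix(ctr + c(-3.6, 0.6, -3.2), nrow(xyz), 3, byrow = TRUE)
  at2 <- at
  at2[, c("x", "y", "z")] <- xyz2
  at2$chain <- "B"
  new_structure(rbind(at, at2), id = id)
}

#' Derive a homologue at controlled sequence identity and coordinate noise
#'
#' Mutates \code{ceiling((1 - identity/100) * n)} residues (residue-name
#' change only; coordinates untouched, so identity and conformation vary
#' independently) and adds i.i.d. Gaussian noise of standard deviation
#' \code{noise} to every polymer atom coordinate.
#'
#' @param structure Parent \code{"pdb_structure"}.
#' @param identity Target sequence identity in percent (0 < identity <= 100).
#' @param noise Coordinate noise sigma in Angstrom (>= 0).
#' @param seed Optional integer seed; fixes the output bit-for-bit.
#' @param id Label for the derived structure.
#' @return A \code{"pdb_structure"}.
#' @export
make_homologue <- function(structure, identity = 100, noise = 0, seed = NULL,
                           id = paste0(structure$id, "_hom")) {
  check_structure(structure)
  if (identity <= 0 || identity > 100)
    stop_lrr("input_error", "identity must be in (0, 100]")
  with_seed(seed, {
    at <- structure$atoms
    poly <- which(at$polymer)
    key <- paste(at$chain, at$resno, at$ins, sep = "\r")[poly]
    res_keys <- unique(key)
    n <- length(res_keys)
    # round at 1e-9 before the ceiling so identities like 95 on n = 40 give
    # exactly (1 - 0.95) * 40 = 2 mutations despite binary representation
    k <- ceiling(round((1 - identity / 100) * n, 9))
    if (k > 0) {
      mutate <- sample(res_keys, k)
      std <- names(AA_3TO1)
      for (m in mutate) {
        rows <- poly[key == m]
        old <- at$resid[rows[1]]
        at$resid[rows] <- sample(setdiff(std, old), 1)
      }
    }
    if (noise > 0) {
      xyz <- as.matrix(at[poly, c("x", "y", "z")])
      at[poly, c("x", "y", "z")] <- xyz + matrix(stats::rnorm(length(xyz), 0, noise),
                                                 nrow(xyz), 3)
    }
    new_structure(at, id = id)
  })
}

#' Bend a chain rigidly about a hinge residue
#'
#' Rotates every polymer residue after the hinge rigidly about an axis through
#' the hinge CA, perpendicular to the local chain direction. The N-terminal
#' half is untouched, so the two halves each remain internally rigid: the
#' fragment-based flexible score stays far below the global r.m.s.d.
#'
#' @param structure A \code{"pdb_structure"}.
#' @param hinge Residue number (author numbering) of the hinge; must be
#'   strictly interior to the chain.
#' @param angle_deg Bend angle in degrees.
#' @param chain_id Chain to bend; defaults to the first polymer chain.
#' @param id Label for the bent structure.
#' @return A \code{"pdb_structure"}.
#' @export
make_hinge_bent <- function(structure, hinge, angle_deg,
                            chain_id = chain_ids(structure)[1],
                            id = paste0(structure$id, "_bent")) {
  check_structure(structure)
  res <- residue_table(structure, chain_id)
  pos <- match(hinge, res$resno)
  if (is.na(pos) || pos <= 1 || pos >= nrow(res))
    stop_lrr("input_error", "hinge residue must be strictly interior to the chain")
  at <- structure$atoms
  ca_row <- which(at$polymer & at$chain == chain_id & at$resno == hinge &
                    at$elety == "CA")[1]
  pivot <- as.numeric(at[ca_row, c("x", "y", "z")])
  # chain direction from atoms the bend leaves in place, so successive bends
  # at the same hinge share an axis and compose exactly
  prev <- which(at$polymer & at$chain == chain_id &
                  at$resno == res$resno[pos - 1] & at$elety == "CA")[1]
  dir <- pivot - as.numeric(at[prev, c("x", "y", "z")])
  # deterministic perpendicular axis: cross the chain direction with the
  # least-aligned Cartesian basis vector
  basis <- diag(3)[, which.min(abs(dir))]
  axis <- cross3(dir, basis)
  R <- rotation_matrix(axis, angle_deg)
  move <- which(at$polymer & at$chain == chain_id & at$resno > hinge)
  if (length(move)) {
    xyz <- as.matrix(at[move, c("x", "y", "z")])
    at[move, c("x", "y", "z")] <-
      sweep(xyz, 2, pivot) %*% t(R) + matrix(pivot, length(move), 3, byrow = TRUE)
  }
  new_structure(at, id = id)
}

#' Generate a complete synthetic benchmark case
#'
#' Builds a ground-truth single-chain fold, a noisy copy standing in for the
#' low-resolution target model, and five homologues spanning sequence
#' identities 95/90/85/78/70 percent with conformational distance from the
#' truth increasing in the same order: coordinate noise sigma 0.15, 0.35 and
#' 0.55 A for the first three, and for the fourth sigma 0.6 A plus a
#' 15-degree hinge bend, so it exceeds the third in both local and global
#' deviation and the construction ordering is unambiguous under any
#' monotone combination of the two. The 70 percent homologue sits below the
#' default identity filter and carries sigma 0.5 A. Labels record which
#' homologue is nearest the ground truth.
#'
#' @param seed Integer seed; fixes all coordinates and mutations.
#' @param n_helix,n_strand Segment lengths of the ground-truth fold.
#' @param target_noise Coordinate noise sigma (A) of the target model.
#' @return A list with elements \code{truth}, \code{target},
#'   \code{homologues} (named list of structures), and \code{labels}
#'   (\code{best}, \code{order} over filter-surviving homologues,
#'   \code{rejected}).
#' @export
make_benchmark_case <- function(seed, n_helix = 26, n_strand = 14,
                                target_noise = 0.4) {
  with_seed(seed, {
    truth <- make_mixed_chain(n_helix, n_strand, id = "truth")
    target <- make_homologue(truth, identity = 100, noise = target_noise,
                             id = "target")
    spec <- list(
      hom95 = list(identity = 95, noise = 0.15, hinge = NULL),
      hom90 = list(identity = 90, noise = 0.35, hinge = NULL),
      hom85 = list(identity = 85, noise = 0.55, hinge = NULL),
      hom78 = list(identity = 78, noise = 0.60, hinge = 15),
      hom70 = list(identity = 70, noise = 0.50, hinge = NULL))
    mid <- truth$atoms$resno[which(truth$atoms$polymer)][1] +
      (n_helix + n_strand) %/% 2
    homologues <- lapply(names(spec), function(nm) {
      s <- spec[[nm]]
      base <- truth
      if (!is.null(s$hinge)) base <- make_hinge_bent(base, mid, s$hinge)
      make_homologue(base, identity = s$identity, noise = s$noise, id = nm)
    })
    names(homologues) <- names(spec)
    list(truth = truth, target = target, homologues = homologues,
         labels = list(best = "hom95",
                       order = c("hom95", "hom90", "hom85", "hom78"),
                       rejected = "hom70"))
  })
}

# evaluate `expr` under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
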