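# External-restraint generation: homologue-derived interatomic distance
# restraints, backbone hydrogen-bond restraints, and jelly-body-style
# self-restraints, plus REFMAC external-restraint keyword serialization.

#' Restraint-generation configuration
#'
#' @param neighbour_cutoff Neighbour-search radius in Angstrom within which
#'   interatomic distances become restraints (default 4.2).
#' @param hbond_target Objective value for hydrogen-bond restraints in
#'   Angstrom (default 2.8, a standard hydrogen-bond length).
#' @param sigma_homologue,sigma_hbond Restraint sigmas in Angstrom for
#'   homologue-derived and hydrogen-bond restraints (default 0.1).
#' @param sigma_jelly Sigma for jelly-body self-restraints (default 0.02;
#'   tight, since these act as a regularizer about the current conformation).
#' @param min_bond_path Minimum covalent bond-path separation: atom pairs
#'   connected by fewer than this many bonds are excluded (default 4, so 1-2,
#'   1-3 and 1-4 pairs — already governed by standard geometry restraints —
#'   are never restrained).
#' @param hbond_max_dist Maximum donor-acceptor N...O distance in Angstrom
#'   for hydrogen-bond detection (default 3.5).
#' @param hbond_min_angle Minimum C=O...N angle in degrees (default 120;
#'   near-linear geometry, which selects the i to i+4 helical bonds and
#'   excludes the bent i+3 contacts).
#' @param hbond_min_sep Minimum sequence separation between donor and
#'   acceptor residues on the same chain (default 2).
#' @return An object of class \code{"restraint_config"}.
#' @export
restraint_config <- function(neighbour_cutoff = 4.2, hbond_target = 2.8,
                             sigma_homologue = 0.1, sigma_hbond = 0.1,
                             sigma_jelly = 0.02, min_bond_path = 4,
                             hbond_max_dist = 3.5, hbond_min_angle = 120,
                             hbond_min_sep = 2) {
  vals <- c(neighbour_cutoff = neighbour_cutoff, hbond_target = hbond_target,
            sigma_homologue = sigma_homologue, sigma_hbond = sigma_hbond,
            sigma_jelly = sigma_jelly, hbond_max_dist = hbond_max_dist)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_lrr("input_error", "all distances and sigmas must be positive")
  structure(list(neighbour_cutoff = neighbour_cutoff,
                 hbond_target = hbond_target,
                 sigma_homologue = sigma_homologue, sigma_hbond = sigma_hbond,
                 sigma_jelly = sigma_jelly,
                 min_bond_path = as.integer(min_bond_path),
                 hbond_max_dist = hbond_max_dist,
                 hbond_min_angle = hbond_min_angle,
                 hbond_min_sep = as.integer(hbond_min_sep)),
            class = "restraint_config")
}

# empty restraint data frame with the canonical column set
empty_restraints <- function() {
  data.frame(chain1 = character(), resi1 = integer(), ins1 = character(),
             atom1 = character(), chain2 = character(), resi2 = integer(),
             ins2 = character(), atom2 = character(), target = numeric(),
             sigma = numeric(), group = integer(), source = character(),
             stringsAsFactors = FALSE)
}

new_restraint_set <- function(df, config, target_id) {
  rownames(df) <- NULL
  structure(list(restraints = df, config = config, target_id = target_id),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  df <- x$restraints
  src <- if (nrow(df)) paste(names(table(df$source)), table(df$source),
                             sep = ":", collapse = ", ") else "none"
  cat(sprintf("<restraint_set for '%s'> %d restraints in %d groups (%s)\n",
              x$target_id, nrow(df), length(unique(df$group)), src))
  invisible(x)
}

## ---- covalent connectivity --------------------------------------------

# indices of polymer, non-hydrogen atoms eligible for restraints
restrainable_atoms <- function(structure) {
  at <- structure$atoms
  which(at$polymer & at$elesy != "H")
}

# adjacency matrix over the given atom rows: standard backbone/CB topology,
# generic intra-residue bonds by distance, and peptide C(i)-N(i+1) links
bond_adjacency <- function(structure, rows) {
  at <- structure$atoms[rows, , drop = FALSE]
  n <- nrow(at)
  A <- matrix(FALSE, n, n)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  reskey <- paste(at$chain, at$resno, at$ins, sep = "\r")
  backbone_pairs <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"))
  for (rk in unique(reskey)) {
    idx <- which(reskey == rk)
    nm <- at$elety[idx]
    for (bp in backbone_pairs) {
      i <- idx[match(bp[1], nm)]
      j <- idx[match(bp[2], nm)]
      if (!is.na(i) && !is.na(j)) A[i, j] <- A[j, i] <- TRUE
    }
    # side-chain atoms beyond CB: covalent if closer than 1.9 A
    side <- idx[!nm %in% c("N", "CA", "C", "O")]
    if (length(side) > 1) {
      for (i in side) for (j in side) if (i < j) {
        if (sum((xyz[i, ] - xyz[j, ])^2) < 1.9^2) A[i, j] <- A[j, i] <- TRUE
      }
    }
    # attach side chain to CB/CA
    cb <- idx[match("CB", nm)]
    if (!is.na(cb)) for (j in side) {
      if (j != cb && sum((xyz[cb, ] - xyz[j, ])^2) < 1.9^2)
        A[cb, j] <- A[j, cb] <- TRUE
    }
  }
  # peptide bonds between consecutive residues of each chain
  for (ch in unique(at$chain)) {
    res <- residue_table(structure, ch)
    rkeys <- paste(ch, res$resno, res$ins, sep = "\r")
    if (nrow(res) < 2) next
    for (i in 1:(nrow(res) - 1)) {
      ci <- which(reskey == rkeys[i] & at$elety == "C")
      ni <- which(reskey == rkeys[i + 1] & at$elety == "N")
      if (length(ci) && length(ni) &&
          sum((xyz[ci[1], ] - xyz[ni[1], ])^2) < 2.5^2)
        A[ci[1], ni[1]] <- A[ni[1], ci[1]] <- TRUE
    }
  }
  A
}

# logical matrix: TRUE where the covalent bond path between two atoms is
# shorter than min_bond_path (these pairs are never restrained); computed
# from powers of the adjacency matrix
short_bond_path <- function(adjacency, min_bond_path) {
  A <- adjacency * 1
  reach <- A
  P <- A
  if (min_bond_path > 2) for (k in 2:(min_bond_path - 1)) {
    P <- P %*% A
    reach <- reach + P
  }
  out <- reach > 0
  diag(out) <- TRUE
  out
}

## ---- homologue restraints ---------------------------------------------

# matched atom pairs between target and reference given a residue pairing:
# returns data.frame(target_row, ref_row) of atom rows (global indices)
match_atoms <- function(target, ref, pairing, target_chain, ref_chain) {
  tres <- residue_table(target, target_chain)
  rres <- residue_table(ref, ref_chain)
  tat <- target$atoms
  rat <- ref$atoms
  out_t <- integer(0)
  out_r <- integer(0)
  for (i in seq_len(nrow(pairing))) {
    tr <- tres[pairing[i, 1], ]
    rr <- rres[pairing[i, 2], ]
    ti <- which(tat$polymer & tat$chain == target_chain & tat$resno == tr$resno &
                  tat$ins == tr$ins & tat$elesy != "H")
    ri <- which(rat$polymer & rat$chain == ref_chain & rat$resno == rr$resno &
                  rat$ins == rr$ins & rat$elesy != "H")
    m <- match(tat$elety[ti], rat$elety[ri])
    ok <- !is.na(m)
    out_t <- c(out_t, ti[ok])
    out_r <- c(out_r, ri[m[ok]])
  }
  data.frame(target_row = out_t, ref_row = out_r)
}

#' Generate homologue-derived external distance restraints
#'
#' For every pair of reference atoms that both match target atoms, lie within
#' the neighbour cutoff of each other in the reference structure, and are not
#' covalently proximal (bond path below \code{min_bond_path}), emits a
#' distance restraint on the corresponding target atom pair whose objective
#' value is the interatomic distance observed in the reference. With several
#' references, restraints on the same target atom pair are alternatives
#' sharing a group id; a downstream minimizer treats the member closest to
#' the current distance as active.
#'
#' @param target A \code{"pdb_structure"} being refined.
#' @param refs List of references; each element a list with
#'   \code{structure}, \code{pairing} (two-column aligned residue-index
#'   matrix), and optionally \code{target_chain} / \code{ref_chain}
#'   (defaulting to first polymer chains). A \code{"homologue_assessment"}
#'   plus its structure can be packaged with [as_restraint_ref()].
#' @param config A [restraint_config()].
#' @return A \code{"restraint_set"}; the \code{source} column carries the
#'   reference structure id of each restraint.
#' @export
generate_homologue_restraints <- function(target, refs,
                                          config = restraint_config()) {
  check_structure(target)
  rows <- restrainable_atoms(target)
  excl <- short_bond_path(bond_adjacency(target, rows), config$min_bond_path)
  pos_in_rows <- integer(nrow(target$atoms))
  pos_in_rows[rows] <- seq_along(rows)
  pieces <- list()
  for (ref in refs) {
    rs <- ref$structure
    tch <- ref$target_chain %||% chain_ids(target)[1]
    rch <- ref$ref_chain %||% chain_ids(rs)[1]
    pairing <- ref$pairing
    if (is.null(pairing) || nrow(pairing) == 0) {
      warning("empty pairing for reference '", rs$id, "'; no restraints generated")
      next
    }
    mm <- match_atoms(target, rs, pairing, tch, rch)
    mm <- mm[mm$target_row %in% rows, , drop = FALSE]
    if (nrow(mm) < 2) next
    rxyz <- coords_matrix(rs, mm$ref_row)
    d <- as.matrix(stats::dist(rxyz))
    m <- nrow(mm)
    pi1 <- pos_in_rows[mm$target_row]
    keep <- which(upper.tri(d) & d <= config$neighbour_cutoff &
                    !excl[pi1, pi1], arr.ind = TRUE)
    if (!nrow(keep)) next
    i <- mm$target_row[keep[, 1]]
    j <- mm$target_row[keep[, 2]]
    at <- target$atoms
    pieces[[length(pieces) + 1]] <- data.frame(
      chain1 = at$chain[i], resi1 = at$resno[i], ins1 = at$ins[i],
      atom1 = at$elety[i], chain2 = at$chain[j], resi2 = at$resno[j],
      ins2 = at$ins[j], atom2 = at$elety[j],
      target = d[keep], sigma = config$sigma_homologue,
      group = NA_integer_, source = rs$id, stringsAsFactors = FALSE)
  }
  df <- if (length(pieces)) do.call(rbind, pieces) else empty_restraints()
  if (nrow(df)) {
    # dedupe within one source, then share a group across sources per pair
    pk <- pair_key(df)
    df <- df[!duplicated(paste(df$source, pk, sep = "\r")), , drop = FALSE]
    df$group <- match(pair_key(df), unique(pair_key(df)))
  }
  new_restraint_set(df, config, target$id)
}

#' Package an assessed homologue for restraint generation
#'
#' @param assessment A \code{"homologue_assessment"} from [assess_homologue()].
#' @param structure The reference \code{"pdb_structure"} the assessment was
#'   computed from.
#' @return A list suitable for the \code{refs} argument of
#'   [generate_homologue_restraints()].
#' @export
as_restraint_ref <- function(assessment, structure) {
  stopifnot(inherits(assessment, "homologue_assessment"))
  list(structure = structure, pairing = assessment$alignment$pairs,
       target_chain = assessment$target_chain, ref_chain = assessment$ref_chain)
}

# canonical unordered atom-pair key
pair_key <- function(df) {
  a <- paste(df$chain1, df$resi1, df$ins1, df$atom1)
  b <- paste(df$chain2, df$resi2, df$ins2, df$atom2)
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## ---- hydrogen-bond restraints -----------------------------------------

#' Detect potential main-chain hydrogen bonds
#'
#' Scans backbone amide nitrogens against backbone carbonyl oxygens of the
#' target structure itself (no reference needed). A pair is reported when the
#' N...O distance is at most \code{hbond_max_dist}, the C=O...N angle is at
#' least \code{hbond_min_angle} degrees (near-linear geometry), and, for
#' atoms on the same chain, the residues are at least \code{hbond_min_sep}
#' apart in sequence. On an ideal alpha-helix this yields exactly the
#' N(i+4) to O(i) pattern.
#'
#' @param structure A \code{"pdb_structure"}.
#' @param config A [restraint_config()] supplying the geometric criteria.
#' @return Data frame with one row per bond: donor (\code{chain1},
#'   \code{resi1}, \code{ins1}, N) and acceptor (\code{chain2}, \code{resi2},
#'   \code{ins2}, O) plus the observed \code{distance}.
#' @export
detect_mainchain_hbonds <- function(structure, config = restraint_config()) {
  check_structure(structure)
  at <- structure$atoms
  out <- list()
  reskey <- paste(at$chain, at$resno, at$ins, sep = "\r")
  # residue position within its chain, for sequence-separation checks
  pos_map <- list()
  for (ch in chain_ids(structure)) {
    res <- residue_table(structure, ch)
    pos_map[[ch]] <- stats::setNames(seq_len(nrow(res)),
                                     paste(ch, res$resno, res$ins, sep = "\r"))
  }
  Ns <- which(at$polymer & at$elety == "N")
  Os <- which(at$polymer & at$elety == "O")
  Cs <- which(at$polymer & at$elety == "C")
  ckey <- reskey[Cs]
  for (i in Ns) {
    ni <- as.numeric(at[i, c("x", "y", "z")])
    for (j in Os) {
      if (reskey[i] == reskey[j]) next
      same_chain <- at$chain[i] == at$chain[j]
      if (same_chain) {
        pi <- pos_map[[at$chain[i]]][reskey[i]]
        pj <- pos_map[[at$chain[j]]][reskey[j]]
        if (abs(pi - pj) < config$hbond_min_sep) next
      }
      oj <- as.numeric(at[j, c("x", "y", "z")])
      d2 <- sum((ni - oj)^2)
      if (d2 > config$hbond_max_dist^2) next
      cj <- Cs[match(reskey[j], ckey)]
      if (is.na(cj)) next
      ang <- vec_angle_deg(as.numeric(at[cj, c("x", "y", "z")]) - oj, ni - oj)
      if (ang < config$hbond_min_angle) next
      out[[length(out) + 1]] <- data.frame(
        chain1 = at$chain[i], resi1 = at$resno[i], ins1 = at$ins[i],
        atom1 = "N", chain2 = at$chain[j], resi2 = at$resno[j],
        ins2 = at$ins[j], atom2 = "O", distance = sqrt(d2),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chain1 = character(), resi1 = integer(), ins1 = character(),
               atom1 = character(), chain2 = character(), resi2 = integer(),
               ins2 = character(), atom2 = character(), distance = numeric(),
               stringsAsFactors = FALSE)
}

#' Generate hydrogen-bond restraints for a structure
#'
#' One restraint per bond found by [detect_mainchain_hbonds()], every one
#' with the same objective value \code{hbond_target} (default 2.8 Angstrom, a
#' standard hydrogen-bond length) regardless of the currently observed
#' distance.
#'
#' @inheritParams detect_mainchain_hbonds
#' @return A \code{"restraint_set"} with source \code{"hbond"}.
#' @export
generate_hbond_restraints <- function(structure, config = restraint_config()) {
  hb <- detect_mainchain_hbonds(structure, config)
  if (!nrow(hb)) return(new_restraint_set(empty_restraints(), config, structure$id))
  df <- hb[, c("chain1", "resi1", "ins1", "atom1",
               "chain2", "resi2", "ins2", "atom2")]
  df$target <- config$hbond_target
  df$sigma <- config$sigma_hbond
  df$source <- "hbond"
  df <- df[!duplicated(pair_key(df)), , drop = FALSE]
  df$group <- seq_len(nrow(df))
  new_restraint_set(df[, names(empty_restraints())], config, structure$id)
}

## ---- jelly-body self-restraints ---------------------------------------

#' Generate jelly-body-style self-restraints
#'
#' For every non-covalently-proximal pair of polymer heavy atoms within the
#' neighbour cutoff, emits a restraint whose objective is the pair's current
#' distance, with a tight sigma. At the moment of generation every residual
#' is zero: the set regularizes subsequent refinement about the current
#' conformation without pulling it anywhere new.
#'
#' @inheritParams detect_mainchain_hbonds
#' @return A \code{"restraint_set"} with source \code{"jelly"}.
#' @export
generate_jelly_restraints <- function(structure, config = restraint_config()) {
  check_structure(structure)
  rows <- restrainable_atoms(structure)
  at <- structure$atoms
  excl <- short_bond_path(bond_adjacency(structure, rows), config$min_bond_path)
  d <- as.matrix(stats::dist(coords_matrix(structure, rows)))
  keep <- which(upper.tri(d) & d <= config$neighbour_cutoff & !excl,
                arr.ind = TRUE)
  if (!nrow(keep))
    return(new_restraint_set(empty_restraints(), config, structure$id))
  i <- rows[keep[, 1]]
  j <- rows[keep[, 2]]
  df <- data.frame(
    chain1 = at$chain[i], resi1 = at$resno[i], ins1 = at$ins[i],
    atom1 = at$elety[i], chain2 = at$chain[j], resi2 = at$resno[j],
    ins2 = at$ins[j], atom2 = at$elety[j], target = d[keep],
    sigma = config$sigma_jelly, group = seq_along(i), source = "jelly",
    stringsAsFactors = FALSE)
  new_restraint_set(df, config, structure$id)
}

## ---- REFMAC keyword serialization -------------------------------------

#' Write a restraint set in REFMAC external-restraint keyword format
#'
#' One `exte dist` line per restraint; insertion codes are written as `.`
#' when absent and distances/sigmas carry three decimals.
#'
#' @param restraints A \code{"restraint_set"}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_refmac_external <- function(restraints, path) {
  stopifnot(inherits(restraints, "restraint_set"))
  df <- restraints$restraints
  ins <- function(x) ifelse(nzchar(x), x, ".")
  lines <- sprintf(paste("exte dist first chain %s resi %d ins %s atom %s",
                         "second chain %s resi %d ins %s atom %s",
                         "value %.3f sigma %.3f type 0"),
                   df$chain1, df$resi1, ins(df$ins1), df$atom1,
                   df$chain2, df$resi2, ins(df$ins2), df$atom2,
                   df$target, df$sigma)
  writeLines(lines, path)
  invisible(path)
}

#' Read a REFMAC external-restraint keyword file
#'
#' Inverse of [write_refmac_external()]. Restraints sharing an unordered atom
#' pair are assigned to the same alternative group, matching the semantics
#' under which a minimizer picks the alternative closest to the current
#' distance.
#'
#' @param path File of `exte dist` keyword lines.
#' @return A \code{"restraint_set"} (source \code{"file"}).
#' @export
read_refmac_external <- function(path) {
  if (!file.exists(path)) stop_lrr("io_error", "file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) < 2 || tolower(tok[1]) != "exte" || tolower(tok[2]) != "dist")
      stop_lrr("parse_error", "line ", ln, ": expected 'exte dist' record")
    val <- function(key) {
      i <- which(tolower(tok) == key)
      if (!length(i) || i[1] == length(tok))
        stop_lrr("parse_error", "line ", ln, ": missing '", key, "' token")
      i
    }
    f <- val("first"); s <- val("second")
    get_after <- function(from, key, upto = length(tok)) {
      i <- which(tolower(tok) == key & seq_along(tok) > from & seq_along(tok) <= upto)
      if (!length(i) || i[1] == length(tok))
        stop_lrr("parse_error", "line ", ln, ": missing '", key, "' token")
      tok[i[1] + 1]
    }
    num <- function(x, what) {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) stop_lrr("parse_error", "line ", ln, ": bad ", what, " '", x, "'")
      v
    }
    ins1 <- get_after(f, "ins", s); ins2 <- get_after(s, "ins")
    rows[[length(rows) + 1]] <- data.frame(
      chain1 = get_after(f, "chain", s),
      resi1 = as.integer(num(get_after(f, "resi", s), "residue number")),
      ins1 = if (ins1 == ".") "" else ins1,
      atom1 = get_after(f, "atom", s),
      chain2 = get_after(s, "chain"),
      resi2 = as.integer(num(get_after(s, "resi"), "residue number")),
      ins2 = if (ins2 == ".") "" else ins2,
      atom2 = get_after(s, "atom"),
      target = num(get_after(2, "value"), "value"),
      sigma = num(get_after(2, "sigma"), "sigma"),
      group = NA_integer_, source = "file", stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_restraints()
  if (nrow(df)) df$group <- match(pair_key(df), unique(pair_key(df)))
  new_restraint_set(df, restraint_config(), "file")
}

# concatenate restraint sets, preserving per-set group semantics by
# renumbering groups on the combined unordered-pair key
combine_restraint_sets <- function(sets, target_id = sets[[1]]$target_id) {
  sets <- Filter(function(s) !is.null(s), sets)
  dfs <- lapply(sets, `[[`, "restraints")
  df <- do.call(rbind, c(dfs, list(empty_restraints())))
  if (nrow(df)) df$group <- match(pair_key(df), unique(pair_key(df)))
  new_restraint_set(df, sets[[1]]$config, target_id)
}
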