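# Homologue assessment: sequence alignment, global CA superposition,
# fragment-based flexible score, and filtering/ranking of reference chains.

#' Globally align two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open 10,
#' extend 0.5), reporting the matched residue-index pairs, percent identity
#' over aligned positions and percent coverage of the target.
#'
#' @param target_seq,ref_seq One-letter amino-acid strings (non-empty).
#' @return An object of class \code{"seq_alignment"}: list with \code{pairs}
#'   (two-column integer matrix of aligned 1-based residue indices, columns
#'   \code{target} and \code{ref}, strictly increasing in both), and
#'   \code{identity} and \code{coverage} percentages.
#' @examples
#' align_sequences("MKVLATGKEW", "MKVLSTGKEW")$identity  # 90
#' @export
align_sequences <- function(target_seq, ref_seq) {
  if (!nzchar(target_seq) || !nzchar(ref_seq))
    stop_lrr("input_error", "cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(target_seq),
    subject = Biostrings::AAString(ref_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ti <- cumsum(p != "-")
  ri <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  pairs <- cbind(target = ti[both], ref = ri[both])
  n_aln <- nrow(pairs)
  identity <- if (n_aln) 100 * sum(p[both] == s[both]) / n_aln else 0
  coverage <- 100 * n_aln / nchar(target_seq)
  structure(list(pairs = pairs, identity = identity, coverage = coverage),
            class = "seq_alignment")
}

#' Fragment-based local backbone similarity (flexible score)
#'
#' Mean backbone (N, CA, C, O) r.m.s.d. over sliding windows of
#' \code{fragment_length} consecutively aligned residues, each window
#' independently superposed. Because each fragment is fitted on its own, the
#' score measures local conformational similarity and is insensitive to
#' rigid-body domain motion, unlike the global r.m.s.d.
#'
#' Windows never cross alignment gaps, and every residue in a window must
#' carry all four backbone atoms in both chains. If no full-length window
#' exists, the longest contiguous run is scored as a single fragment provided
#' it has at least 5 residues; otherwise the score is undefined and an error
#' of class \code{lrr_undefined_score} is raised.
#'
#' @param target,ref \code{"pdb_structure"} objects.
#' @param pairing Two-column matrix of aligned residue indices (1-based,
#'   columns target/ref), e.g. from [align_sequences()].
#' @param target_chain,ref_chain Chain ids; default to the first polymer
#'   chain of each structure.
#' @param fragment_length Window length in residues (default 9).
#' @return Mean fragment r.m.s.d. in Angstrom.
#' @export
flexible_score <- function(target, ref, pairing,
                           target_chain = chain_ids(target)[1],
                           ref_chain = chain_ids(ref)[1],
                           fragment_length = 9) {
  frags <- aligned_backbone_runs(target, ref, pairing, target_chain, ref_chain)
  runs <- frags$runs
  scores <- numeric(0)
  for (run in runs) {
    m <- length(run)
    if (m < fragment_length) next
    for (start in 1:(m - fragment_length + 1)) {
      w <- run[start:(start + fragment_length - 1)]
      scores <- c(scores, superposed_rmsd(frags$target_bb[bb_rows(w), ],
                                          frags$ref_bb[bb_rows(w), ]))
    }
  }
  if (length(scores)) return(mean(scores))
  # fallback: single fragment on the longest run when it has >= 5 residues
  lens <- vapply(runs, length, 1L)
  if (length(lens) && max(lens) >= 5) {
    run <- runs[[which.max(lens)]]
    return(superposed_rmsd(frags$target_bb[bb_rows(run), ],
                           frags$ref_bb[bb_rows(run), ]))
  }
  stop_lrr("undefined_score",
           "flexible score undefined: fewer than 5 contiguously aligned ",
           "residues with complete backbones")
}

# rows of the stacked 4-atom-per-residue backbone matrix for residue set w
bb_rows <- function(w) as.vector(t(outer(4 * (w - 1), 1:4, `+`)))

# shared helper: backbone coordinates of aligned residue pairs, split into
# runs contiguous in both chains with all 4 backbone atoms present
aligned_backbone_runs <- function(target, ref, pairing, target_chain, ref_chain) {
  tres <- residue_table(target, target_chain)
  rres <- residue_table(ref, ref_chain)
  if (is.null(dim(pairing)) || nrow(pairing) == 0)
    stop_lrr("input_error", "empty residue pairing")
  bb <- c("N", "CA", "C", "O")
  tcoords <- lapply(bb, function(a) atom_coords_by_residue(target, target_chain, tres, a))
  rcoords <- lapply(bb, function(a) atom_coords_by_residue(ref, ref_chain, rres, a))
  np <- nrow(pairing)
  tbb <- matrix(NA_real_, 4 * np, 3)
  rbb <- matrix(NA_real_, 4 * np, 3)
  for (k in 1:4) {
    tbb[seq(k, by = 4, length.out = np), ] <- tcoords[[k]][pairing[, 1], , drop = FALSE]
    rbb[seq(k, by = 4, length.out = np), ] <- rcoords[[k]][pairing[, 2], , drop = FALSE]
  }
  complete <- vapply(seq_len(np), function(i) {
    rows <- bb_rows(i)
    !anyNA(tbb[rows, ]) && !anyNA(rbb[rows, ])
  }, TRUE)
  # runs: consecutive in the pairing, step of exactly 1 in both chains,
  # complete backbones throughout
  runs <- list()
  cur <- integer(0)
  for (i in seq_len(np)) {
    ok <- complete[i] &&
      (length(cur) == 0 ||
         (pairing[i, 1] == pairing[cur[length(cur)], 1] + 1 &&
          pairing[i, 2] == pairing[cur[length(cur)], 2] + 1))
    if (complete[i] && ok) {
      cur <- c(cur, i)
    } else {
      if (length(cur)) runs[[length(runs) + 1]] <- cur
      cur <- if (complete[i]) i else integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  list(target_bb = tbb, ref_bb = rbb, runs = runs,
       target_res = tres, ref_res = rres)
}

#' Assess one homologous reference chain against a target chain
#'
#' Runs sequence alignment, whole-chain Kabsch superposition on matched CA
#' atoms (global r.m.s.d.) and the fragment-based [flexible_score()], and
#' combines the two r.m.s.d. values into the rank score by a simple sum.
#'
#' @inheritParams flexible_score
#' @return An object of class \code{"homologue_assessment"}: list with
#'   \code{ref_id}, \code{ref_chain}, \code{target_chain}, \code{identity},
#'   \code{coverage}, \code{global_rmsd}, \code{flexible_score},
#'   \code{rank_score} (= global + flexible, Angstrom) and the
#'   \code{alignment}.
#' @export
assess_homologue <- function(target, ref,
                             target_chain = chain_ids(target)[1],
                             ref_chain = chain_ids(ref)[1]) {
  aln <- align_sequences(extract_chain_sequence(target, target_chain),
                         extract_chain_sequence(ref, ref_chain))
  if (nrow(aln$pairs) == 0)
    stop_lrr("assessment_error", "no aligned residues between '", target$id,
             "' and '", ref$id, "'")
  tres <- residue_table(target, target_chain)
  rres <- residue_table(ref, ref_chain)
  tca <- atom_coords_by_residue(target, target_chain, tres, "CA")[aln$pairs[, 1], , drop = FALSE]
  rca <- atom_coords_by_residue(ref, ref_chain, rres, "CA")[aln$pairs[, 2], , drop = FALSE]
  ok <- stats::complete.cases(tca) & stats::complete.cases(rca)
  if (sum(ok) < 3)
    stop_lrr("assessment_error", "fewer than 3 matched CA atoms")
  global <- superpose(tca[ok, , drop = FALSE], rca[ok, , drop = FALSE])$rmsd
  flex <- flexible_score(target, ref, aln$pairs, target_chain, ref_chain)
  structure(list(ref_id = ref$id, ref_chain = ref_chain,
                 target_chain = target_chain,
                 identity = aln$identity, coverage = aln$coverage,
                 global_rmsd = global, flexible_score = flex,
                 rank_score = global + flex, alignment = aln),
            class = "homologue_assessment")
}

#' Filter homologue assessments on identity and coverage thresholds
#'
#' Keeps exactly those assessments with sequence identity and target coverage
#' at or above the thresholds; the defaults (75/75) reject reference chains
#' below 75 percent identity or covering less than 75 percent of the target,
#' with boundary values retained.
#'
#' @param assessments List of \code{"homologue_assessment"} objects.
#' @param min_identity,min_coverage Thresholds in percent.
#' @return Filtered list (possibly empty).
#' @export
filter_homologues <- function(assessments, min_identity = 75, min_coverage = 75) {
  keep <- vapply(assessments, function(a)
    a$identity >= min_identity && a$coverage >= min_coverage, TRUE)
  assessments[keep]
}

#' Rank homologue assessments, best first
#'
#' Orders by ascending rank score (global + local r.m.s.d.); ties broken by
#' higher sequence identity, then by input order.
#'
#' @param assessments List of \code{"homologue_assessment"} objects.
#' @return The list reordered best-first.
#' @seealso [order_by_global_rmsd()] for the "most different homologues"
#'   ordering used by the distant-homologue protocols.
#' @export
rank_homologues <- function(assessments) {
  if (!length(assessments)) return(assessments)
  rs <- vapply(assessments, `[[`, 1, "rank_score")
  id <- vapply(assessments, `[[`, 1, "identity")
  assessments[order(rs, -id, seq_along(assessments))]
}

#' Order homologue assessments by decreasing global r.m.s.d.
#'
#' The "most different" ordering: largest global r.m.s.d. first, ties by
#' input order.
#'
#' @inheritParams rank_homologues
#' @return The list reordered most-different-first.
#' @export
order_by_global_rmsd <- function(assessments) {
  if (!length(assessments)) return(assessments)
  g <- vapply(assessments, `[[`, 1, "global_rmsd")
  assessments[order(-g, seq_along(assessments))]
}

#' Tabulate homologue assessments
#'
#' @inheritParams rank_homologues
#' @return Data frame with one row per assessment.
#' @export
assessment_table <- function(assessments) {
  do.call(rbind, lapply(assessments, function(a)
    data.frame(ref_id = a$ref_id, ref_chain = a$ref_chain,
               identity = a$identity, coverage = a$coverage,
               global_rmsd = a$global_rmsd, flexible_score = a$flexible_score,
               rank_score = a$rank_score, stringsAsFactors = FALSE)))
}

#' @export
print.homologue_assessment <- function(x, ...) {
  cat(sprintf(paste0("<homologue_assessment '%s' chain %s> identity %.1f%%, ",
                     "coverage %.1f%%\n  global rmsd %.3f A + flexible %.3f A ",
                     "= rank score %.3f A\n"),
              x$ref_id, x$ref_chain, x$identity, x$coverage,
              x$global_rmsd, x$flexible_score, x$rank_score))
  invisible(x)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d aligned pairs, identity %.1f%%, coverage %.1f%%\n",
              nrow(x$pairs), x$identity, x$coverage))
  invisible(x)
}
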