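# Independent oracles and fixture helpers shared across the test files.
# Every oracle re-derives its quantity by brute force (exhaustive search,
# explicit loops, or a third-party implementation) without touching the code
# path it checks.

## ---- brute-force rotation-search superposition oracle ------------------

# least rmsd over rigid motions, by exhaustive Euler-angle search: 15-degree
# coarse grid, 1-degree local grid around the best cell, then simplex polish
grid_superpose_rmsd <- function(A, B) {
  P <- sweep(B, 2, colMeans(B))
  Q <- sweep(A, 2, colMeans(A))
  f <- function(ang) {
    R <- rotation_matrix(c(0, 0, 1), ang[1]) %*%
      rotation_matrix(c(0, 1, 0), ang[2]) %*%
      rotation_matrix(c(0, 0, 1), ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- c(0, 0, 0)
  bv <- f(best)
  for (a in seq(0, 345, 15)) for (b in seq(0, 180, 15)) for (cc in seq(0, 345, 15)) {
    v <- f(c(a, b, cc))
    if (v < bv) { bv <- v; best <- c(a, b, cc) }
  }
  for (a in seq(best[1] - 7, best[1] + 7, 1))
    for (b in seq(best[2] - 7, best[2] + 7, 1))
      for (cc in seq(best[3] - 7, best[3] + 7, 1)) {
        v <- f(c(a, b, cc))
        if (v < bv) { bv <- v; best <- c(a, b, cc) }
      }
  o <- stats::optim(best, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  min(bv, o$value)
}

## ---- covalent connectivity + bond-path oracle --------------------------

# bonds among the polymer heavy atoms of `structure`, derived independently:
# backbone/CB topology by name, other same-residue pairs under 1.9 A, and
# peptide C-N links between consecutive residues under 2.5 A
oracle_bond_list <- function(structure) {
  at <- structure$atoms
  rows <- which(at$polymer & at$elesy != "H")
  at <- at[rows, , drop = FALSE]
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bonds <- list()
  add <- function(i, j) bonds[[length(bonds) + 1]] <<- c(i, j)
  rk <- paste(at$chain, at$resno, at$ins)
  named <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (rk[i] == rk[j]) {
      pair_named <- any(vapply(named, function(p)
        setequal(c(at$elety[i], at$elety[j]), p), TRUE))
      backbone_i <- at$elety[i] %in% c("N", "CA", "C", "O")
      backbone_j <- at$elety[j] %in% c("N", "CA", "C", "O")
      if (pair_named) add(i, j)
      else if (!(backbone_i && backbone_j) && d < 1.9 &&
               !(at$elety[i] %in% c("N", "C", "O")) &&
               !(at$elety[j] %in% c("N", "C", "O"))) add(i, j)
    } else if (at$chain[i] == at$chain[j] && d < 2.5 &&
               ((at$elety[i] == "C" && at$elety[j] == "N") ||
                (at$elety[i] == "N" && at$elety[j] == "C"))) {
      # peptide link only between consecutive residues of the chain
      res <- residue_table(structure, at$chain[i])
      pi <- match(paste(at$chain[i], at$resno[i], at$ins[i]),
                  paste(at$chain[i], res$resno, res$ins))
      pj <- match(paste(at$chain[j], at$resno[j], at$ins[j]),
                  paste(at$chain[j], res$resno, res$ins))
      if (abs(pi - pj) == 1) add(i, j)
    }
  }
  list(rows = rows, bonds = bonds, n = n)
}

# TRUE at [i, j] when the bond path between oracle atoms i and j is shorter
# than min_path, by breadth-first search over the oracle bond list
oracle_short_path <- function(bl, min_path) {
  n <- bl$n
  adj <- vector("list", n)
  for (b in bl$bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  out <- matrix(FALSE, n, n)
  diag(out) <- TRUE
  for (s in seq_len(n)) {
    depth <- rep(Inf, n)
    depth[s] <- 0
    frontier <- s
    for (d in seq_len(min_path - 1)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[depth[nxt] == Inf]
      if (!length(nxt)) break
      depth[nxt] <- d
      frontier <- nxt
    }
    out[s, depth < min_path] <- TRUE
  }
  out
}

## ---- restraint-generation oracles --------------------------------------

# canonical sorted representation of a restraint table for set comparison
restraint_signature <- function(df, digits = 6) {
  a <- paste(df$chain1, df$resi1, df$ins1, df$atom1)
  b <- paste(df$chain2, df$resi2, df$ins2, df$atom2)
  key <- ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  sort(paste(key, round(df$target, digits), df$source))
}

# all-pairs enumeration oracle for jelly self-restraints
oracle_jelly_signature <- function(structure, config) {
  bl <- oracle_bond_list(structure)
  short <- oracle_short_path(bl, config$min_bond_path)
  at <- structure$atoms[bl$rows, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  out <- character(0)
  for (i in seq_len(bl$n)) for (j in seq_len(bl$n)) {
    if (i >= j || short[i, j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > config$neighbour_cutoff) next
    a <- paste(at$chain[i], at$resno[i], at$ins[i], at$elety[i])
    b <- paste(at$chain[j], at$resno[j], at$ins[j], at$elety[j])
    key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
    out <- c(out, paste(key, round(d, 6), "jelly"))
  }
  sort(out)
}

# all-pairs enumeration oracle for homologue-derived restraints from one
# reference (source tag = reference structure id)
oracle_homologue_signature <- function(target, ref, pairing, config,
                                       target_chain = chain_ids(target)[1],
                                       ref_chain = chain_ids(ref)[1]) {
  bl <- oracle_bond_list(target)
  short <- oracle_short_path(bl, config$min_bond_path)
  tat <- target$atoms
  rat <- ref$atoms
  tres <- residue_table(target, target_chain)
  rres <- residue_table(ref, ref_chain)
  # matched atoms: same name within aligned residue pairs, heavy atoms only
  mt <- integer(0); mr <- integer(0)
  for (p in seq_len(nrow(pairing))) {
    trow <- tres[pairing[p, 1], ]
    rrow <- rres[pairing[p, 2], ]
    ti <- which(tat$polymer & tat$chain == target_chain &
                  tat$resno == trow$resno & tat$ins == trow$ins & tat$elesy != "H")
    for (i in ti) {
      j <- which(rat$polymer & rat$chain == ref_chain & rat$resno == rrow$resno &
                   rat$ins == rrow$ins & rat$elety == tat$elety[i])
      if (length(j)) { mt <- c(mt, i); mr <- c(mr, j[1]) }
    }
  }
  pos <- match(mt, bl$rows)
  out <- character(0)
  for (u in seq_along(mt)) for (v in seq_along(mt)) {
    if (u >= v) next
    d <- sqrt(sum((as.numeric(rat[mr[u], c("x", "y", "z")]) -
                   as.numeric(rat[mr[v], c("x", "y", "z")]))^2))
    if (d > config$neighbour_cutoff) next
    if (short[pos[u], pos[v]]) next
    a <- paste(tat$chain[mt[u]], tat$resno[mt[u]], tat$ins[mt[u]], tat$elety[mt[u]])
    b <- paste(tat$chain[mt[v]], tat$resno[mt[v]], tat$ins[mt[v]], tat$elety[mt[v]])
    key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
    out <- c(out, paste(key, round(d, 6), ref$id))
  }
  sort(out)
}

## ---- hydrogen-bond oracle ----------------------------------------------

# all-pairs N/O scan with the geometric criteria recomputed from scratch
oracle_hbond_count <- function(structure, config = restraint_config()) {
  at <- structure$atoms
  Ns <- which(at$polymer & at$elety == "N")
  Os <- which(at$polymer & at$elety == "O")
  count <- 0
  for (i in Ns) for (j in Os) {
    if (at$chain[i] == at$chain[j]) {
      res <- residue_table(structure, at$chain[i])
      pos_i <- match(paste(at$resno[i], at$ins[i]), paste(res$resno, res$ins))
      pos_j <- match(paste(at$resno[j], at$ins[j]), paste(res$resno, res$ins))
      if (abs(pos_i - pos_j) < config$hbond_min_sep) next
    }
    ni <- as.numeric(at[i, c("x", "y", "z")])
    oj <- as.numeric(at[j, c("x", "y", "z")])
    if (sqrt(sum((ni - oj)^2)) > config$hbond_max_dist) next
    cj <- which(at$polymer & at$chain == at$chain[j] & at$resno == at$resno[j] &
                  at$ins == at$ins[j] & at$elety == "C")
    if (!length(cj)) next
    co <- as.numeric(at[cj[1], c("x", "y", "z")])
    u <- co - oj
    v <- ni - oj
    ang <- acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (ang >= config$hbond_min_angle) count <- count + 1
  }
  count
}

## ---- protocol-enumeration dedup oracle ---------------------------------

oracle_protocol_count <- function(rank_ids, distant_ids, maxk = 3) {
  n <- length(rank_ids)
  sets <- list()
  if (n > 0) {
    for (k in seq_len(min(maxk, n))) sets <- c(sets, list(sort(rank_ids[1:k])))
    for (k in seq_len(min(maxk, n))) sets <- c(sets, list(sort(distant_ids[1:k])))
    sets <- c(sets, list(sort(rank_ids)))
  }
  length(unique(sets)) + 2  # + ERB + JELLY
}

## ---- fixture helpers ---------------------------------------------------

# a minimal structure of isolated CA-only residues at given coordinates
points_structure <- function(coords, chain = "A", id = "points") {
  coords <- as.matrix(coords)
  df <- data.frame(type = "ATOM", chain = chain, resno = seq_len(nrow(coords)),
                   ins = "", resid = "ALA", elety = "CA", elesy = "C",
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   o = 1, b = 0, polymer = TRUE, stringsAsFactors = FALSE)
  lrrefine:::new_structure(df, id = id)
}

# fixed-width PDB ATOM line for hand-built fixtures
pdb_atom_line <- function(serial, name, alt, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, x, y, z, occ, b)
}

# a homologue-assessment stub for filter/rank/enumeration tests
fake_assessment <- function(id, identity = 90, coverage = 100,
                            global_rmsd = 0.5, flexible = 0.2) {
  structure(list(ref_id = id, ref_chain = "A", target_chain = "A",
                 identity = identity, coverage = coverage,
                 global_rmsd = global_rmsd, flexible_score = flexible,
                 rank_score = global_rmsd + flexible,
                 alignment = NULL),
            class = "homologue_assessment")
}

# CA rmsd between two structures after optimal superposition
ca_rmsd <- function(a, b) {
  ca <- function(s) coords_matrix_of(s, "CA")
  superpose(ca(a), ca(b))$rmsd
}

coords_matrix_of <- function(s, elety = NULL) {
  at <- s$atoms
  if (!is.null(elety)) at <- at[at$elety == elety, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

# small random structure fixture for oracle-equivalence sweeps
random_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(6:16, 1)
  kind <- sample(c("helix", "strand", "mixed"), 1)
  s <- switch(kind,
              helix = make_ideal_helix(n),
              strand = make_ideal_strand(n),
              mixed = make_mixed_chain(max(n - 4, 1), 4))
  make_homologue(s, identity = 100, noise = stats::runif(1, 0, 0.3),
                 seed = seed + 1000, id = paste0("fix", seed))
}
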