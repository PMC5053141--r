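test_that("global alignment reports identity and coverage as hand-counted", {
  s20 <- "MKVLATGEWQRNDFYHPSCI"
  a <- align_sequences(s20, s20)
  expect_equal(a$identity, 100)
  expect_equal(a$coverage, 100)
  expect_equal(nrow(a$pairs), 20)

  sub5 <- "MKVLGSGEWARNDFYHPACV"  # 5 substitutions -> 15/20 identical
  b <- align_sequences(s20, sub5)
  expect_equal(b$identity, 75)
  expect_equal(b$coverage, 100)

  half <- substr(s20, 1, 10)      # 10/20 target residues alignable
  cc <- align_sequences(s20, half)
  expect_equal(cc$coverage, 50)
  expect_equal(cc$identity, 100)

  expect_error(align_sequences("", "MKV"), class = "lrr_input_error")
})

test_that("aligned index pairs increase strictly in both sequences", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 25, replace = TRUE), collapse = "")
    p <- align_sequences(a, b)$pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) > 0))
    }
    expect_gte(p[1, 1], 1)
    expect_lte(p[nrow(p), 1], 30)
  }
})

test_that("superposition recovers rigid motions exactly and is invariant to them", {
  set.seed(17)
  A <- matrix(rnorm(30), 10, 3)
  expect_lt(superpose(A, A)$rmsd, 1e-12)

  moved <- A %*% t(rotation_matrix(c(0, 0, 1), 90)) +
    matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
  sp <- superpose(A, moved)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(sp, moved), A, tolerance = 1e-9,
               ignore_attr = TRUE)

  # rmsd unchanged when either input is rigidly moved
  B <- A + matrix(rnorm(30, 0, 0.5), 10, 3)
  base <- superpose(A, B)$rmsd
  for (s in 1:5) {
    set.seed(s)
    ax <- rnorm(3)
    R <- rotation_matrix(ax, runif(1, 0, 360))
    shift <- matrix(rnorm(3, 0, 10), 10, 3, byrow = TRUE)
    expect_lt(abs(superpose(A, B %*% t(R) + shift)$rmsd - base), 1e-6)
    expect_lt(abs(superpose(A %*% t(R) + shift, B)$rmsd - base), 1e-6)
  }
})

test_that("superposition rejects degenerate input", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "lrr_geometry_error")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line + 0, line), class = "lrr_geometry_error")
})

test_that("Kabsch rmsd matches the rotation-grid search oracle", {
  set.seed(23)
  A <- matrix(rnorm(12, sd = 2), 4, 3)
  B <- A
  B[2, ] <- B[2, ] + c(0.4, 0, 0)  # one point displaced by 0.4 A
  expect_lt(abs(superpose(A, B)$rmsd - grid_superpose_rmsd(A, B)), 1e-3)
})

test_that("flexible score is zero for identical chains and local for hinge bends", {
  h <- make_ideal_helix(24)
  pairing <- cbind(1:24, 1:24)
  expect_lt(flexible_score(h, h, pairing), 1e-9)

  bent <- make_hinge_bent(h, 12, 30)
  a <- assess_homologue(h, bent)
  expect_gt(a$global_rmsd, 1)
  expect_lt(a$flexible_score, a$global_rmsd / 3)

  # per-window oracle: mean of independently fitted 9-residue backbone windows
  bb <- c("N", "CA", "C", "O")
  win_rmsd <- vapply(1:16, function(i) {
    sel_t <- h$atoms$resno %in% i:(i + 8) & h$atoms$elety %in% bb
    sel_b <- bent$atoms$resno %in% i:(i + 8) & bent$atoms$elety %in% bb
    bio3d::rmsd(as.vector(t(coords_matrix_of(h)[sel_t, ])),
                as.vector(t(coords_matrix_of(bent)[sel_b, ])), fit = TRUE)
  }, 1)
  expect_equal(a$flexible_score, mean(win_rmsd), tolerance = 1e-4)
})

test_that("short alignments fall back to a single fragment when >= 5 residues", {
  h6 <- make_ideal_helix(6)
  pert <- make_homologue(h6, identity = 100, noise = 0.2, seed = 2, id = "p6")
  pairing <- cbind(1:6, 1:6)
  got <- flexible_score(h6, pert, pairing)
  bb <- h6$atoms$elety %in% c("N", "CA", "C", "O")
  direct <- superpose(coords_matrix_of(h6)[bb, ], coords_matrix_of(pert)[bb, ])$rmsd
  expect_equal(got, direct, tolerance = 1e-9)

  h4 <- make_ideal_helix(4)
  expect_error(flexible_score(h4, h4, cbind(1:4, 1:4)),
               class = "lrr_undefined_score")
})

test_that("a chain assessed against itself scores zero everywhere", {
  h <- make_ideal_helix(15)
  a <- assess_homologue(h, h)
  expect_equal(a$identity, 100)
  expect_equal(a$coverage, 100)
  expect_lt(a$global_rmsd, 1e-9)
  expect_lt(a$flexible_score, 1e-9)
  expect_equal(a$rank_score, a$global_rmsd + a$flexible_score)
})

test_that("assessment of a perturbed copy matches an independent fitted rmsd", {
  h <- make_ideal_helix(20)
  hom <- make_homologue(h, identity = 100, noise = 0.3, seed = 9, id = "pert")
  a <- assess_homologue(h, hom)
  expect_gt(a$global_rmsd, 0.2)
  expect_lt(a$global_rmsd, 0.5)
  oracle <- bio3d::rmsd(as.vector(t(coords_matrix_of(h, "CA"))),
                        as.vector(t(coords_matrix_of(hom, "CA"))), fit = TRUE)
  expect_equal(a$global_rmsd, oracle, tolerance = 1e-3)
})

test_that("an unrelated chain still assesses, with low identity", {
  h <- make_ideal_helix(30)
  stranger <- make_homologue(make_ideal_strand(30), identity = 1, noise = 0,
                             seed = 4, id = "stranger")
  a <- assess_homologue(h, stranger)
  expect_lt(a$identity, 30)
  expect_true(is.finite(a$rank_score))
})

test_that("identity/coverage filtering keeps boundary values and rejects below", {
  ids <- c(70, 74.9, 75, 80)
  as_list <- lapply(seq_along(ids), function(i)
    fake_assessment(paste0("h", i), identity = ids[i], coverage = 100))
  kept <- filter_homologues(as_list)
  expect_equal(vapply(kept, `[[`, 1, "identity"), c(75, 80))

  low_cov <- fake_assessment("lc", identity = 90, coverage = 60)
  expect_length(filter_homologues(list(low_cov)), 0)
  expect_length(filter_homologues(list()), 0)
})

test_that("ranking orders by summed rmsd with identity then input-order tie-breaks", {
  a <- fake_assessment("a", global_rmsd = 0.5, flexible = 0.2)  # 0.7
  b <- fake_assessment("b", global_rmsd = 0.4, flexible = 0.4)  # 0.8
  r <- rank_homologues(list(b, a))
  expect_equal(vapply(r, `[[`, "", "ref_id"), c("a", "b"))
  expect_equal(rank_homologues(list(a))[[1]]$ref_id, "a")

  t1 <- fake_assessment("i90", identity = 90, global_rmsd = 0.3, flexible = 0.3)
  t2 <- fake_assessment("i95", identity = 95, global_rmsd = 0.3, flexible = 0.3)
  expect_equal(rank_homologues(list(t1, t2))[[1]]$ref_id, "i95")
  # permuting input preserves the ordering apart from documented tie-breaks
  expect_equal(rank_homologues(list(t2, t1))[[1]]$ref_id, "i95")

  d <- order_by_global_rmsd(list(a, b))
  expect_equal(vapply(d, `[[`, "", "ref_id"), c("a", "b"))  # 0.5 > 0.4
})
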