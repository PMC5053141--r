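test_that("ideal helices have the expected size and geometry", {
  h <- make_ideal_helix(12)
  expect_equal(nrow(h$atoms), 60)  # 5 atoms per residue
  ca <- coords_matrix_of(h, "CA")
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.05))  # consecutive CA-CA ~3.8 A
  expect_equal(nrow(make_ideal_helix(1)$atoms), 5)
  expect_error(make_ideal_helix(0), class = "lrr_input_error")
})

test_that("homologue generation mutates the requested residue count and nothing else", {
  h <- make_ideal_helix(20)
  hom <- make_homologue(h, identity = 75, noise = 0, seed = 11)
  target <- extract_chain_sequence(h, "A")
  got <- extract_chain_sequence(hom, "A")
  n_mut <- sum(strsplit(target, "")[[1]] != strsplit(got, "")[[1]])
  expect_equal(n_mut, 5)  # ceiling(0.25 * 20)
  expect_equal(coords_matrix_of(hom), coords_matrix_of(h))  # names only

  ident <- make_homologue(h, identity = 100, noise = 0)
  expect_identical(ident$atoms[, -match("resid", names(ident$atoms))],
                   h$atoms[, -match("resid", names(h$atoms))])
  expect_equal(extract_chain_sequence(ident, "A"), target)
})

test_that("requested identity and noise are realized within tolerance", {
  h <- make_ideal_helix(24)  # 120 atoms
  for (s in 1:5) {
    id_req <- sample(c(70, 78, 85, 92), 1)
    hom <- make_homologue(h, identity = id_req, noise = 0.4, seed = s)
    a <- strsplit(extract_chain_sequence(h, "A"), "")[[1]]
    b <- strsplit(extract_chain_sequence(hom, "A"), "")[[1]]
    realized <- 100 * mean(a == b)
    expect_lte(abs(realized - id_req), 100 / 24 + 1e-9)  # within 1 residue
    disp <- sqrt(mean((coords_matrix_of(hom) - coords_matrix_of(h))^2))
    expect_lt(abs(disp - 0.4) / 0.4, 0.15)  # per-coordinate RMS within 15%
  }
})

test_that("generators are bit-for-bit deterministic under a fixed seed", {
  h <- make_ideal_helix(15)
  a <- make_homologue(h, identity = 80, noise = 0.3, seed = 42)
  b <- make_homologue(h, identity = 80, noise = 0.3, seed = 42)
  expect_identical(a$atoms, b$atoms)
  c1 <- make_benchmark_case(7)
  c2 <- make_benchmark_case(7)
  expect_identical(c1$target$atoms, c2$target$atoms)
  expect_identical(lapply(c1$homologues, `[[`, "atoms"),
                   lapply(c2$homologues, `[[`, "atoms"))
})

test_that("hinge bending is rigid, composable and rejects terminal hinges", {
  h <- make_ideal_helix(24)
  expect_equal(make_hinge_bent(h, 12, 0)$atoms, h$atoms, tolerance = 1e-12)
  b30 <- make_hinge_bent(h, 12, 30)
  b15x2 <- make_hinge_bent(make_hinge_bent(h, 12, 15), 12, 15)
  expect_lt(max(abs(coords_matrix_of(b30) - coords_matrix_of(b15x2))), 1e-6)
  # N-terminal half untouched
  keep <- h$atoms$resno <= 12
  expect_equal(coords_matrix_of(b30)[keep, ], coords_matrix_of(h)[keep, ])
  expect_error(make_hinge_bent(h, 1, 30), class = "lrr_input_error")
  expect_error(make_hinge_bent(h, 24, 30), class = "lrr_input_error")
})

test_that("benchmark cases carry consistent labels and identities", {
  bc <- make_benchmark_case(3)
  expect_named(bc$homologues, c("hom95", "hom90", "hom85", "hom78", "hom70"))
  expect_equal(bc$labels$best, "hom95")
  tseq <- strsplit(extract_chain_sequence(bc$truth, "A"), "")[[1]]
  for (nm in names(bc$homologues)) {
    hseq <- strsplit(extract_chain_sequence(bc$homologues[[nm]], "A"), "")[[1]]
    realized <- 100 * mean(tseq == hseq)
    requested <- as.numeric(sub("hom", "", nm))
    expect_lte(abs(realized - requested), 100 / length(tseq) + 1e-9)
  }
  # conformational distance to truth increases along the labelled order
  d <- vapply(bc$labels$order, function(nm)
    ca_rmsd(bc$truth, bc$homologues[[nm]]), 1)
  expect_true(all(diff(d) > 0))
})

test_that("the antiparallel sheet fixture has two chains in contact", {
  sh <- make_antiparallel_sheet(6)
  expect_setequal(chain_ids(sh), c("A", "B"))
  a <- coords_matrix_of(sh)[sh$atoms$chain == "A", ]
  b <- coords_matrix_of(sh)[sh$atoms$chain == "B", ]
  gap <- min(as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                                 nrow(a) + seq_len(nrow(b))])
  expect_lt(gap, 3.5)
})
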