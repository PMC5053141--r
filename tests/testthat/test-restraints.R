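test_that("restraint configuration rejects non-positive distances and sigmas", {
  expect_s3_class(restraint_config(), "restraint_config")
  expect_error(restraint_config(neighbour_cutoff = 0), class = "lrr_input_error")
  expect_error(restraint_config(sigma_jelly = -1), class = "lrr_input_error")
})

test_that("homologue restraints record reference distances and respect the cutoff", {
  h <- make_ideal_helix(12)
  ref <- make_homologue(h, identity = 100, noise = 0, id = "ref1")
  aln <- align_sequences(extract_chain_sequence(h, "A"),
                         extract_chain_sequence(ref, "A"))
  rs <- generate_homologue_restraints(
    h, list(list(structure = ref, pairing = aln$pairs)))
  df <- rs$restraints
  expect_gt(nrow(df), 0)
  expect_true(all(df$sigma == 0.1))
  expect_true(all(df$source == "ref1"))

  # objective distances equal the (identical) reference geometry
  at <- h$atoms
  akey <- paste(at$chain, at$resno, at$ins, at$elety)
  i <- match(paste(df$chain1, df$resi1, df$ins1, df$atom1), akey)
  j <- match(paste(df$chain2, df$resi2, df$ins2, df$atom2), akey)
  d_now <- sqrt(rowSums((coords_matrix_of(h)[i, ] - coords_matrix_of(h)[j, ])^2))
  expect_equal(df$target, d_now, tolerance = 1e-9)
  expect_true(all(df$target <= 4.2))

  # covalently bonded N-CA pairs are never restrained
  bonded <- df$resi1 == df$resi2 &
    ((df$atom1 == "N" & df$atom2 == "CA") | (df$atom1 == "CA" & df$atom2 == "N"))
  expect_false(any(bonded))
  # 1-3 pairs (two bonds apart) excluded as well
  nc <- df$resi1 == df$resi2 &
    ((df$atom1 == "N" & df$atom2 == "C") | (df$atom1 == "C" & df$atom2 == "N"))
  expect_false(any(nc))
})

test_that("restraints never reference atoms absent from the target", {
  h <- make_ideal_helix(8)
  longer <- make_homologue(make_ideal_helix(12), identity = 100, noise = 0.1,
                           seed = 3, id = "long")
  aln <- align_sequences(extract_chain_sequence(h, "A"),
                         extract_chain_sequence(longer, "A"))
  rs <- generate_homologue_restraints(
    h, list(list(structure = longer, pairing = aln$pairs)))
  at <- h$atoms
  akey <- paste(at$chain, at$resno, at$ins, at$elety)
  expect_true(all(paste(rs$restraints$chain1, rs$restraints$resi1,
                        rs$restraints$ins1, rs$restraints$atom1) %in% akey))
  expect_true(all(paste(rs$restraints$chain2, rs$restraints$resi2,
                        rs$restraints$ins2, rs$restraints$atom2) %in% akey))
})

test_that("k copies of one reference give the same pairs with k alternatives each", {
  h <- make_ideal_helix(10)
  base <- make_homologue(h, identity = 100, noise = 0.1, seed = 8, id = "c1")
  aln <- align_sequences(extract_chain_sequence(h, "A"),
                         extract_chain_sequence(base, "A"))
  one <- generate_homologue_restraints(
    h, list(list(structure = base, pairing = aln$pairs)))
  copies <- lapply(1:3, function(k) {
    s <- base
    s$id <- paste0("c", k)
    list(structure = s, pairing = aln$pairs)
  })
  three <- generate_homologue_restraints(h, copies)
  expect_equal(length(unique(three$restraints$group)),
               length(unique(one$restraints$group)))
  expect_true(all(table(three$restraints$group) == 3))
})

test_that("an empty pairing yields an empty set with a warning", {
  h <- make_ideal_helix(6)
  expect_warning(
    rs <- generate_homologue_restraints(
      h, list(list(structure = h, pairing = cbind(integer(0), integer(0))))),
    "empty pairing")
  expect_equal(nrow(rs$restraints), 0)
})

test_that("the ideal helix shows the i to i+4 hydrogen-bond ladder", {
  h <- make_ideal_helix(12)
  hb <- detect_mainchain_hbonds(h)
  expect_equal(nrow(hb), 8)
  expect_equal(sort(hb$resi1 - hb$resi2), rep(4L, 8))  # donor N is 4 ahead
  expect_equal(sort(hb$resi2), 1:8)
  expect_equal(nrow(detect_mainchain_hbonds(make_ideal_strand(10))), 0)
})

test_that("sheet hydrogen bonds match the all-pairs geometric oracle", {
  sh <- make_antiparallel_sheet(6)
  hb <- detect_mainchain_hbonds(sh)
  expect_equal(nrow(hb), oracle_hbond_count(sh))
  expect_gt(sum(hb$chain1 != hb$chain2), 0)  # inter-strand bonds present
})

test_that("hydrogen-bond restraints all carry the standard objective length", {
  h <- make_ideal_helix(12)
  rs <- generate_hbond_restraints(h)
  expect_equal(nrow(rs$restraints), 8)
  expect_true(all(rs$restraints$target == 2.8))
  expect_true(all(rs$restraints$sigma == 0.1))

  mixed <- make_mixed_chain(12, 8)
  expect_equal(nrow(generate_hbond_restraints(mixed)$restraints),
               nrow(detect_mainchain_hbonds(mixed)))

  none <- make_ideal_strand(8)
  expect_equal(nrow(generate_hbond_restraints(none)$restraints), 0)
})

test_that("jelly restraints self-restrain current distances under the cutoff", {
  h <- make_ideal_helix(12)
  rs <- generate_jelly_restraints(h)
  df <- rs$restraints
  at <- h$atoms
  akey <- paste(at$chain, at$resno, at$ins, at$elety)
  i <- match(paste(df$chain1, df$resi1, df$ins1, df$atom1), akey)
  j <- match(paste(df$chain2, df$resi2, df$ins2, df$atom2), akey)
  d_now <- sqrt(rowSums((coords_matrix_of(h)[i, ] - coords_matrix_of(h)[j, ])^2))
  expect_equal(df$target, d_now, tolerance = 1e-9)  # zero residual at start
  expect_true(all(df$sigma == 0.02))

  far <- points_structure(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  expect_equal(nrow(generate_jelly_restraints(far)$restraints), 0)
})

test_that("generated restraint sets equal the brute-force enumeration oracle", {
  cfg <- restraint_config()
  h <- make_ideal_helix(12)  # 60-atom helix
  expect_equal(restraint_signature(generate_jelly_restraints(h, cfg)$restraints),
               oracle_jelly_signature(h, cfg))

  ref <- make_homologue(h, identity = 90, noise = 0.2, seed = 5, id = "refx")
  aln <- align_sequences(extract_chain_sequence(h, "A"),
                         extract_chain_sequence(ref, "A"))
  got <- generate_homologue_restraints(
    h, list(list(structure = ref, pairing = aln$pairs)), cfg)
  expect_equal(restraint_signature(got$restraints),
               oracle_homologue_signature(h, ref, aln$pairs, cfg))
})

test_that("REFMAC keyword serialization round-trips all fields", {
  h <- make_ideal_helix(12)
  rs <- generate_hbond_restraints(h)
  f <- withr::local_tempfile(fileext = ".txt")
  write_refmac_external(rs, f)
  lines <- readLines(f)
  expect_length(lines, 8)
  expect_true(all(grepl("value 2.800", lines, fixed = TRUE)))
  expect_true(all(grepl("^exte dist first chain", lines)))

  back <- read_refmac_external(f)
  cols <- c("chain1", "resi1", "ins1", "atom1",
            "chain2", "resi2", "ins2", "atom2")
  expect_equal(back$restraints[cols], rs$restraints[cols], ignore_attr = TRUE)
  expect_equal(back$restraints$target, round(rs$restraints$target, 3))
  expect_equal(back$restraints$sigma, round(rs$restraints$sigma, 3))

  jelly <- generate_jelly_restraints(make_ideal_helix(6))
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_refmac_external(jelly, f2)
  back2 <- read_refmac_external(f2)
  expect_equal(nrow(back2$restraints), nrow(jelly$restraints))
  expect_equal(back2$restraints$target, round(jelly$restraints$target, 3))
})

test_that("malformed keyword lines fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "exte dist first chain A resi 1 ins . atom N second chain A resi 5 ins . atom O value 2.800 sigma 0.100 type 0",
    "exte dist first chain A resi 2 ins . atom N second chain A resi 6 ins . atom O value 2.800 type 0"), f)
  err <- tryCatch(read_refmac_external(f), error = function(e) e)
  expect_s3_class(err, "lrr_parse_error")
  expect_match(conditionMessage(err), "line 2")
  expect_match(conditionMessage(err), "sigma")
})
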