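test_that("built-in enzymes carry canonical palindromic recognition sites", {
  expect_equal(as.character(restriction_enzyme("EcoRV")$recognition),
               "GATATC")
  expect_equal(as.character(restriction_enzyme("SacII")$recognition),
               "CCGCGG")
  expect_equal(as.character(restriction_enzyme("HindIII")$recognition),
               "AAGCTT")
  expect_equal(as.character(restriction_enzyme("EcoRI")$recognition),
               "GAATTC")
  for (e in c("EcoRV", "SacII", "HindIII", "EcoRI"))
    expect_true(is_palindromic(restriction_enzyme(e)))
  expect_false(is_palindromic(restriction_enzyme("SapI", "GCTCTTC")))
  expect_error(restriction_enzyme("NoSuchEnzyme"), "unknown enzyme")
  expect_error(restriction_enzyme("Tiny", "ACG"), "at least 4")
})

test_that("identity-policy MBS places the miRNA's own bases in the bulge", {
  m <- mir21()
  mb <- build_mbs(m, design_params())
  expect_equal(as.character(mb$seq), "UCAACAUCACAGAGAUAAGCUA")
  expect_equal(mb$bulge_positions_mbs, 10:13)
  # degenerate bulge -> exact reverse complement
  perfect <- build_mbs(m, design_params(bulge_window = NULL))
  expect_equal(as.character(perfect$seq),
               as.character(reverse_complement(m$seq)))
  # duplex check: exactly the bulge width mismatched, all in window
  d <- pair_duplex(m, mb)
  expect_equal(d$n_mismatch, 4L)
  expect_equal(d$mismatch_positions, 10:13)
})

test_that("no bulge base pairs (WC or wobble) under either policy", {
  set.seed(20)
  for (i in 1:20) {
    m <- rand_mirna()
    for (pol in c("identity", "seeded_random")) {
      p <- design_params(mismatch_policy = pol, rng_seed = i)
      mb <- build_mbs(m, p)
      d <- pair_duplex(m, mb)
      bulge <- oracle_chars(d$pairing)[10:13]
      expect_true(all(bulge == "."),
                  label = sprintf("policy %s, miRNA %s", pol,
                                  as.character(m$seq)))
      # outside the bulge the site is a perfect complement
      expect_equal(d$n_mismatch, 4L)
    }
  }
  # identity policy: bulge bases are exactly the miRNA bases at the window
  m <- mir21()
  mb <- build_mbs(m, design_params())
  site <- oracle_chars(as.character(mb$seq))
  mirv <- oracle_chars(as.character(m$seq))
  L <- length(m)
  for (q in 10:13) expect_equal(site[L + 1 - q], mirv[q])
})

test_that("seeded_random mismatch choice is deterministic per seed", {
  m <- mir21()
  p1 <- design_params(mismatch_policy = "seeded_random", rng_seed = 7)
  expect_equal(as.character(build_mbs(m, p1)$seq),
               as.character(build_mbs(m, p1)$seq))
})

test_that("designs with invalid bulge windows are refused", {
  m <- mir21()
  expect_error(build_mbs(m, design_params(bulge_window = c(5, 9))),
               "overlaps the seed")
  expect_error(build_mbs(m, design_params(bulge_window = c(20, 25))),
               "outside")
  short <- mirna("m15", "ACGGACGAACGGACG")  # 15 nt, window 10-13 fits
  expect_silent(build_mbs(short, design_params()))
})

test_that("spacers respect length, determinism and context constraints", {
  m <- mir21()
  p <- design_params()
  mb <- build_mbs(m, p)
  expect_equal(as.character(make_spacer(design_params(spacer_len = 0),
                                        mb, mb, m)), "")
  s1 <- make_spacer(p, mb, mb, m, rng_seed = 1)
  s2 <- make_spacer(p, mb, mb, m, rng_seed = 1)
  expect_equal(as.character(s1), as.character(s2))
  expect_equal(length(s1), 4L)
  # scanner oracle: the joined window gains no target site overlapping
  # the spacer
  join <- paste0(as.character(mb$seq), as.character(s1),
                 as.character(mb$seq))
  hits <- find_seed_matches(rna(join), m)
  lo <- length(mb$seq); hi <- lo + 4L
  expect_false(any(hits$start < hi & hits$end > lo))
})

test_that("assembled insert obeys the closed-form length and layout", {
  m <- mir21()
  sc <- assemble_insert(m, design_params())
  expect_equal(length(sc$insert), 190L)  # 6 + 7*22 + 6*4 + 6
  expect_equal(substr(as.character(sc$insert), 1, 6), "GATATC")
  expect_equal(substr(as.character(sc$insert), 185, 190), "CCGCGG")
  expect_equal(nrow(sc$features), 15L)
  one <- assemble_insert(m, design_params(n_mbs = 1))
  expect_equal(length(one$insert), 34L)  # 6 + 22 + 6
  expect_equal(nrow(one$features), 3L)
  # closed form over random miRNAs and parameter draws
  set.seed(21)
  for (i in 1:25) {
    mm <- rand_mirna()
    n <- sample(1:8, 1)
    sl <- sample(0:6, 1)
    p <- design_params(n_mbs = n, spacer_len = sl, rng_seed = i)
    sci <- assemble_insert(mm, p)
    expect_equal(length(sci$insert),
                 6L + n * length(mm) + (n - 1L) * sl + 6L)
    f <- sci$features
    expect_equal(f$start[1], 0L)
    expect_equal(f$end[nrow(f)], length(sci$insert))
    expect_true(all(f$start[-1] == f$end[-nrow(f)]))
  }
})

test_that("assembly is deterministic for a fixed seed", {
  m <- mir21()
  a <- assemble_insert(m, design_params(rng_seed = 5))
  b <- assemble_insert(m, design_params(rng_seed = 5))
  expect_equal(as.character(a$insert), as.character(b$insert))
  # fixed spacer policy reuses one spacer everywhere
  fx <- assemble_insert(m, design_params(spacer_policy = "fixed"))
  sp <- fx$features[fx$features$kind == "spacer", ]
  spacer_seqs <- substring(as.character(fx$insert), sp$start + 1, sp$end)
  expect_equal(length(unique(spacer_seqs)), 1L)
})

test_that("validation passes on the default design with a decoy panel", {
  m <- mir21()
  sc <- assemble_insert(m, design_params())
  rep <- validate_construct(sc, m, fixture_decoy_panel(20))
  expect_true(rep$pass)
  expect_equal(nrow(rep$checks), 5L)
  expect_true(all(rep$checks$pass))
})

test_that("validation catches corrupted constructs as report rows", {
  m <- mir21()
  sc <- assemble_insert(m, design_params())
  # corrupt a seed-pairing position of MBS1 (transcript position 7 is the
  # site base opposite miRNA position 22 .. position 28 opposite pos 1;
  # seed-opposing bases sit near the MBS 3' end)
  res <- oracle_chars(as.character(sc$insert))
  mbs1_end <- 28L  # MBS1 occupies insert positions 7..28
  pos <- mbs1_end - 3L  # opposes miRNA position 4, inside the seed
  res[pos] <- setdiff(c("A", "C", "G", "T"), res[pos])[1]
  bad <- sc
  bad$insert <- dna(paste(res, collapse = ""))
  rep <- validate_construct(bad, m)
  expect_false(rep$pass)
  fails <- rep$checks$check[!rep$checks$pass]
  expect_true(any(c("site_count", "mbs_duplex") %in% fails))

  # plant a HindIII site inside the first spacer (positions 29..32 + tail)
  res2 <- oracle_chars(as.character(sc$insert))
  res2[29:34] <- oracle_chars("AAGCTT")
  bad2 <- sc
  bad2$insert <- dna(paste(res2, collapse = ""))
  rep2 <- validate_construct(bad2, m)
  rs_row <- rep2$checks[rep2$checks$check == "restriction", ]
  expect_false(rs_row$pass)
  expect_match(rs_row$detail, "HindIII")
})

test_that("validation reports serialize to TSV and JSON", {
  sc <- assemble_insert(mir21(), design_params())
  rep <- validate_construct(sc)
  tsv <- validation_tsv(rep)
  expect_match(tsv, "^check\\tpass\\tdetail\n")
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 6L)
  js <- jsonlite::fromJSON(validation_json(rep))
  expect_true(js$pass)
  expect_equal(nrow(js$checks), 5L)
})
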