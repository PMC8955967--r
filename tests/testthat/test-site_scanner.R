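test_that("seed scanning finds and classifies the canonical site classes", {
  m <- mir21()
  # perfect-complement site: miR-21 starts with U, so the base opposite
  # position 1 is A and the site is an 8mer
  site <- as.character(reverse_complement(m$seq))
  hits <- find_seed_matches(rna(site), m)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$site_class, "8mer")
  expect_equal(find_seed_matches(rna(strrep("A", 30)), m) |> nrow(), 0L)

  # strip the 8mer down class by class
  core <- substr(site, 15, 21)          # pairs miRNA 2-8 (7mer-m8)
  expect_equal(find_seed_matches(rna(paste0("CC", core, "CC")), m)$site_class,
               "7mer-m8")
  core6A <- paste0(substr(site, 16, 21), "A")  # pairs 2-7 plus A1
  expect_equal(find_seed_matches(rna(paste0("CC", core6A, "CC")), m)$site_class,
               "7mer-A1")
  core6 <- substr(site, 16, 21)
  expect_equal(find_seed_matches(rna(paste0("CC", core6, "CC")), m)$site_class,
               "6mer")
})

test_that("full-site scanning reproduces the designed site inventory", {
  m <- mir21()
  sc <- assemble_insert(m, design_params())
  tx <- transcribe(sc$insert)
  full <- find_full_sites(tx, m, bulge_window = c(10, 13))
  expect_equal(nrow(full), 7L)
  expect_true(all(full$site_class == "full_bulged"))
  for (mm in full$mismatch_positions) expect_equal(mm, 10:13)
  # site starts coincide with the MBS feature table
  expect_equal(full$start,
               sc$features$start[sc$features$kind == "MBS"])

  perfect <- assemble_insert(m, design_params(bulge_window = NULL))
  fp <- find_full_sites(transcribe(perfect$insert), m)
  expect_equal(nrow(fp), 7L)
  expect_true(all(fp$site_class == "full_perfect"))

  # decoy with an unrelated seed sees nothing
  decoy <- fixture_decoy_panel(1)[[1]]
  expect_equal(nrow(find_full_sites(tx, decoy, c(10, 13))), 0L)
})

test_that("restriction scanning finds flank sites and nothing else", {
  expect_equal(find_restriction_sites(dna("GATATC"), "EcoRV")$start, 0L)
  sc <- assemble_insert(mir21(), design_params())
  rs <- find_restriction_sites(sc$insert, c("EcoRV", "SacII"))
  expect_equal(rs$enzyme, c("EcoRV", "SacII"))
  expect_equal(rs$start, c(0L, 184L))
  expect_equal(nrow(find_restriction_sites(sc$insert,
                                           c("HindIII", "EcoRI"))), 0L)
  # non-palindromic enzymes are scanned on both strands
  s <- dna(paste0("AAAA", "GCTCTTC", "AAAA",
                  as.character(reverse_complement(dna("GCTCTTC"))), "AA"))
  sap <- restriction_enzyme("SapI", "GCTCTTC")
  hits <- find_restriction_sites(s, list(sap))
  expect_setequal(hits$strand, c("-", "+"))
})

test_that("scanners agree with the naive brute-force oracle", {
  set.seed(30)
  m_short <- mirna("seedy", "UAGCUUAUCAGACUGAUGUUGA")
  for (i in 1:12) {
    L <- sample(30:300, 1)
    x <- rand_rna_str(L)
    # seed the string with a few planted motifs so hits actually occur
    site <- as.character(reverse_complement(m_short$seq))
    at <- sample(1:(L - 30), 1)
    x <- paste0(substr(x, 1, at), substr(site, 14, 22),
                substr(x, at + 10, L))
    for (circ in c(FALSE, TRUE)) {
      s <- rna(x, topology = if (circ) "circular" else "linear")
      got <- find_seed_matches(s, m_short)
      want <- oracle_seed_scan(x, m_short, circular = circ)
      expect_equal(got$start, want$start, label = paste("seed starts, L =", L))
      expect_equal(got$site_class, want$site_class)
      gotf <- find_full_sites(s, m_short, c(10, 13))
      wantf <- oracle_full_scan(x, m_short, c(10, 13), circular = circ)
      expect_equal(gotf$start, wantf$start)
      d <- chartr("U", "T", x)
      sd <- dna(d, topology = if (circ) "circular" else "linear")
      gotr <- find_restriction_sites(sd, "EcoRV")
      expect_equal(gotr$start, oracle_site_search(d, "GATATC",
                                                  circular = circ))
    }
  }
})

test_that("full sites against a full sponge agree with the oracle", {
  m <- mir21()
  tx <- transcribe(assemble_insert(m, design_params())$insert)
  want <- oracle_full_scan(as.character(tx), m, c(10, 13))
  got <- find_full_sites(tx, m, c(10, 13))
  expect_equal(got$start, want$start)
  expect_equal(got$site_class, want$site_class)
})

test_that("linear results equal circular results without junction hits", {
  set.seed(31)
  m <- rand_mirna(22)
  for (i in 1:8) {
    x <- paste0(rand_rna_str(40),
                as.character(reverse_complement(m$seq)), rand_rna_str(40))
    lin <- find_seed_matches(rna(x), m)
    circ <- find_seed_matches(rna(x, topology = "circular"), m)
    circ_nonspan <- circ[!circ$spans_junction, , drop = FALSE]
    rownames(circ_nonspan) <- NULL
    expect_equal(lin, circ_nonspan)
  }
})

test_that("a rotated hit is recovered across the junction", {
  set.seed(33)
  m <- mir21()
  site <- as.character(reverse_complement(m$seq))
  x <- paste0(site, rand_rna_str(30))
  base <- rna(x, topology = "circular")
  hits0 <- find_full_sites(base, m, c(10, 13))
  expect_equal(nrow(hits0), 1L)
  # rotate so the site straddles the origin
  rot <- rotate(base, 10)
  hits <- find_full_sites(rot, m, c(10, 13))
  expect_equal(nrow(hits), 1L)
  expect_true(hits$spans_junction)
  seedhits <- find_seed_matches(rot, m)
  expect_equal(nrow(seedhits), 1L)
})

test_that("perfect full sites are also strong seed matches", {
  set.seed(32)
  for (i in 1:10) {
    m <- rand_mirna()
    x <- paste0(rand_rna_str(20), as.character(reverse_complement(m$seq)),
                rand_rna_str(20))
    fp <- find_full_sites(rna(x), m)
    fp <- fp[fp$site_class == "full_perfect", , drop = FALSE]
    seeds <- find_seed_matches(rna(x), m)
    strong <- seeds[seeds$site_class %in% c("7mer-m8", "8mer"), ,
                    drop = FALSE]
    for (st in fp$start) {
      # the strong seed hit sits at the 3' end of the full site: an 8mer
      # ending at st + L when miRNA position 1 is U (A opposite it), a
      # 7mer-m8 ending one base earlier otherwise
      expect_true(any(strong$end %in% (st + length(m) - 0:1)))
    }
  }
})

test_that("hit tables render as BED-like TSV", {
  m <- mir21()
  hits <- find_seed_matches(rna(as.character(reverse_complement(m$seq))), m)
  txt <- write_hits_tsv(hits, seq_id = "mbs")
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "seq_id\tstart\tend\tsite_class\tmirna_id\tstrand")
  expect_equal(lines[2], "mbs\t14\t22\t8mer\thsa-miR-21-5p\t+")
})
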