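# Independent brute-force oracles used to cross-check the package's
# scanners and transforms. Everything here is written as plain per-base
# loops with explicit lookup tables, deliberately sharing no code with
# the implementation.

ORACLE_WC <- c(A = "U", C = "G", G = "C", U = "A")

oracle_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

rand_rna_str <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

rand_mirna <- function(L = sample(20:24, 1), id = "rand-mir") {
  mirna(id, rand_rna_str(L))
}

# per-base complement-then-reverse
oracle_revcomp <- function(x, alphabet = "RNA") {
  comp_tab <- if (alphabet == "RNA") ORACLE_WC
              else c(A = "T", C = "G", G = "C", T = "A")
  ch <- oracle_chars(x)
  out <- character(length(ch))
  for (i in seq_along(ch)) out[length(ch) - i + 1L] <- comp_tab[[ch[i]]]
  paste(out, collapse = "")
}

# are two strings rotations of each other? (brute force over shifts)
oracle_rotation_equal <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  L <- nchar(a)
  for (k in 0:(L - 1)) {
    rot <- paste0(substr(a, k + 1, L), substr(a, 1, k))
    if (rot == b) return(TRUE)
  }
  FALSE
}

# character of a sequence at 1-based position i, wrapping when circular;
# NA outside bounds for linear input
oracle_char_at <- function(chars, i, circular) {
  L <- length(chars)
  if (circular) return(chars[((i - 1) %% L) + 1])
  if (i < 1 || i > L) return(NA_character_)
  chars[i]
}

# naive seed-class scan: for every start, test core pairing of miRNA
# positions 2-7 base by base, then the m8 and A1 extensions
oracle_seed_scan <- function(seq_str, m, circular = FALSE) {
  s <- oracle_chars(seq_str)
  mirv <- oracle_chars(as.character(m$seq))
  L <- length(s)
  n_starts <- if (circular) L else L - 5L
  out <- list()
  for (i in seq_len(max(0L, n_starts))) {
    ok <- TRUE
    for (k in 1:6) {
      ch <- oracle_char_at(s, i + k - 1L, circular)
      # core position k of the site faces miRNA position 8-k
      if (is.na(ch) || ch != ORACLE_WC[[mirv[8 - k]]]) { ok <- FALSE; break }
    }
    if (!ok) next
    left <- oracle_char_at(s, i - 1L, circular)
    right <- oracle_char_at(s, i + 6L, circular)
    m8 <- !is.na(left) && left == ORACLE_WC[[mirv[8]]]
    a1 <- !is.na(right) && right == "A"
    if (m8 && a1) { cls <- "8mer"; st <- i - 1L; w <- 8L }
    else if (m8) { cls <- "7mer-m8"; st <- i - 1L; w <- 7L }
    else if (a1) { cls <- "7mer-A1"; st <- i; w <- 7L }
    else { cls <- "6mer"; st <- i; w <- 6L }
    st0 <- if (circular) (st - 1L) %% L else st - 1L
    out[[length(out) + 1L]] <- data.frame(
      start = st0, end = st0 + w, site_class = cls,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# naive full-site scan: O(L * n) sliding comparison with an explicit
# pair table; wobble counts as mismatch
oracle_full_scan <- function(seq_str, m, bulge_window = NULL,
                             circular = FALSE) {
  s <- oracle_chars(seq_str)
  mirv <- oracle_chars(as.character(m$seq))
  L <- length(s)
  Lm <- length(mirv)
  n_starts <- if (circular) L else L - Lm + 1L
  out <- list()
  for (i in seq_len(max(0L, n_starts))) {
    mm <- integer(0)
    ok <- TRUE
    for (q in seq_len(Lm)) {
      ch <- oracle_char_at(s, i + (Lm - q), circular)
      if (is.na(ch)) { ok <- FALSE; break }
      if (ch != ORACLE_WC[[mirv[q]]]) mm <- c(mm, q)
    }
    if (!ok) next
    mm <- sort(mm)
    if (!length(mm)) cls <- "full_perfect"
    else {
      if (is.null(bulge_window)) next
      if (mm[1] < bulge_window[1] || mm[length(mm)] > bulge_window[2]) next
      if ((mm[length(mm)] - mm[1] + 1L) != length(mm)) next
      cls <- "full_bulged"
    }
    out[[length(out) + 1L]] <- data.frame(
      start = i - 1L, site_class = cls, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), site_class = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# naive substring search for restriction recognition sites
oracle_site_search <- function(seq_str, pattern, circular = FALSE) {
  s <- oracle_chars(seq_str)
  p <- oracle_chars(pattern)
  L <- length(s)
  n_starts <- if (circular) L else L - length(p) + 1L
  hits <- integer(0)
  for (i in seq_len(max(0L, n_starts))) {
    ok <- TRUE
    for (k in seq_along(p)) {
      ch <- oracle_char_at(s, i + k - 1L, circular)
      if (is.na(ch) || ch != p[k]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# Some random targets inherently embed a forbidden recognition sequence
# in their own binding sites (the MBS is the target's complement, so the
# designer cannot avoid it); the validator rightly flags those. Design
# properties therefore sample targets without such an inherent clash,
# while keeping any hit that overlaps a spacer (which the spacer search
# must prevent) so spacer bugs still surface.
assemble_designable <- function(rng_seed) {
  repeat {
    m <- rand_mirna()
    sc <- tryCatch(assemble_insert(m, design_params(rng_seed = rng_seed)),
                   error = function(e) NULL)
    if (is.null(sc)) next
    p <- sc$params
    rs <- find_restriction_sites(sc$insert, p$forbidden_enzymes)
    L <- length(sc$insert)
    terminal <- (rs$enzyme == p$flank5$name & rs$start == 0L) |
      (rs$enzyme == p$flank3$name & rs$start == L - rs$width)
    rs <- rs[!terminal, , drop = FALSE]
    sp <- sc$features[sc$features$kind == "spacer", , drop = FALSE]
    in_spacer <- vapply(seq_len(nrow(rs)), function(i)
      any(rs$start[i] < sp$end & rs$start[i] + rs$width[i] > sp$start),
      TRUE)
    if (nrow(rs) == 0L || all(in_spacer))
      return(list(mirna = m, construct = sc))
  }
}

# fixture decoy panel used across tests: screened against the default
# construct transcript so the off-target check is deterministic
fixture_decoy_panel <- function(n = 20) {
  tx <- backsplice(assemble_insert(mir21(), design_params()))
  generate_decoy_panel(mir21(), n = n, rng_seed = 42, screen = tx$seq)
}
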