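# Circular inputs are scanned with the doubled-sequence technique: hits
# whose start lies in the first copy are kept, so every junction-spanning
# occurrence is found exactly once.

.as_scan_rna <- function(s) {
  s <- as_nt_seq(s)
  if (s$alphabet == "DNA") transcribe(s) else s
}

.empty_sites <- function() {
  data.frame(mirna_id = character(0), start = integer(0), end = integer(0),
             site_class = character(0), spans_junction = logical(0),
             stringsAsFactors = FALSE)
}

# all 1-based start positions of fixed pattern pat in subject string w
.pattern_starts <- function(pat, w) {
  if (nchar(w) < nchar(pat)) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::RNAString(pat),
                                   Biostrings::RNAString(w))
  as.integer(Biostrings::start(hits))
}

#' Find canonical seed-match sites
#'
#' Scans a sequence for positions that Watson-Crick-pair the miRNA seed
#' and classifies each hit with the canonical target-site taxonomy:
#' \describe{
#'   \item{6mer}{pairs miRNA positions 2-7.}
#'   \item{7mer-m8}{pairs positions 2-8.}
#'   \item{7mer-A1}{pairs 2-7 with an A opposite miRNA position 1.}
#'   \item{8mer}{pairs 2-8 with an A opposite position 1.}
#' }
#' Each seed-core occurrence is reported once with its best (largest)
#' class; G:U wobble counts as non-pairing. DNA input is transcribed
#' before scanning; circular input is scanned across the back-splice
#' junction and junction-spanning hits are flagged.
#'
#' @param s `nt_seq` (RNA or DNA, linear or circular) or character.
#' @param m target [mirna()].
#' @return data.frame with columns `mirna_id`, `start`, `end` (0-based
#'   half-open on the canonical rotation; `end` may exceed the sequence
#'   length for junction-spanning hits), `site_class`, `spans_junction`.
#' @export
find_seed_matches <- function(s, m) {
  stopifnot(inherits(m, "mirna"))
  s <- .as_scan_rna(s)
  L <- length(s)
  if (L < 6L) return(.empty_sites())
  circ <- s$topology == "circular"
  w <- if (circ) paste0(s$residues, s$residues) else s$residues
  nw <- nchar(w)
  mirc <- .chars(m$seq$residues)
  core <- reverse_complement(rna(paste(mirc[2:7], collapse = "")))$residues
  starts <- .pattern_starts(core, w)
  starts <- starts[starts <= L]
  if (!length(starts)) return(.empty_sites())

  comp_m8 <- .WC[[mirc[8]]]
  rows <- lapply(starts, function(c0) {
    # base pairing miRNA position 8 sits immediately 5' of the core;
    # on a circle the neighbour of position 1 is position L
    left <- if (c0 > 1L) substr(w, c0 - 1L, c0 - 1L)
            else if (circ) substr(w, L, L) else NA_character_
    right <- if (c0 + 6L <= nw) substr(w, c0 + 6L, c0 + 6L)
             else NA_character_
    m8 <- !is.na(left) && left == comp_m8
    a1 <- !is.na(right) && right == "A"
    if (m8 && a1) { cls <- "8mer";    st <- c0 - 1L; en <- c0 + 6L }
    else if (m8)  { cls <- "7mer-m8"; st <- c0 - 1L; en <- c0 + 5L }
    else if (a1)  { cls <- "7mer-A1"; st <- c0;      en <- c0 + 6L }
    else          { cls <- "6mer";    st <- c0;      en <- c0 + 5L }
    width <- en - st + 1L
    st0 <- if (circ) (st - 1L) %% L else st - 1L
    data.frame(mirna_id = m$id, start = st0, end = st0 + width,
               site_class = cls, spans_junction = circ && st0 + width > L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find full (perfect or bulged) miRNA sites
#'
#' Slides a miRNA-length window over the sequence and keeps windows
#' that pair the miRNA perfectly at every position (`full_perfect`) or
#' perfectly everywhere except a contiguous mismatch block lying wholly
#' inside `bulge_window` (`full_bulged`). Wobble pairs count as
#' mismatches. Mismatch positions are reported in miRNA coordinates.
#'
#' @param s `nt_seq` (RNA or DNA, linear or circular) or character.
#' @param m target [mirna()].
#' @param bulge_window 1-based inclusive miRNA-position pair within
#'   which mismatches are tolerated, or NULL for perfect sites only.
#' @return data.frame like [find_seed_matches()], with an additional
#'   list column `mismatch_positions`.
#' @export
find_full_sites <- function(s, m, bulge_window = NULL) {
  stopifnot(inherits(m, "mirna"))
  if (!is.null(bulge_window)) {
    bulge_window <- as.integer(bulge_window)
    stopifnot(length(bulge_window) == 2L, bulge_window[1] >= 1L,
              bulge_window[1] <= bulge_window[2],
              bulge_window[2] <= length(m))
  }
  s <- .as_scan_rna(s)
  L <- length(s)
  Lm <- length(m)
  circ <- s$topology == "circular"
  empty <- .empty_sites()
  empty$mismatch_positions <- I(list())
  if ((circ && Lm > L) || (!circ && Lm > L)) return(empty)
  w <- if (circ) paste0(s$residues, s$residues) else s$residues
  wch <- .chars(w)
  rc <- .chars(reverse_complement(m$seq)$residues)
  n_starts <- if (circ) L else L - Lm + 1L
  rows <- list()
  for (i in seq_len(n_starts)) {
    win <- wch[i:(i + Lm - 1L)]
    mm_site <- which(win != rc)
    if (!length(mm_site)) {
      cls <- "full_perfect"
      mirpos <- integer(0)
    } else {
      if (is.null(bulge_window)) next
      mirpos <- sort(Lm + 1L - mm_site)
      contiguous <- (mirpos[length(mirpos)] - mirpos[1] + 1L) ==
        length(mirpos)
      if (!contiguous || mirpos[1] < bulge_window[1] ||
          mirpos[length(mirpos)] > bulge_window[2]) next
      cls <- "full_bulged"
    }
    rows[[length(rows) + 1L]] <- list(start = i - 1L, cls = cls,
                                      mirpos = mirpos)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(
    mirna_id = m$id,
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "start") + Lm,
    site_class = vapply(rows, `[[`, "", "cls"),
    spans_junction = circ & (vapply(rows, `[[`, 0L, "start") + Lm > L),
    stringsAsFactors = FALSE)
  out$mismatch_positions <- I(lapply(rows, `[[`, "mirpos"))
  rownames(out) <- NULL
  out
}

#' Find restriction recognition sites
#'
#' Reports every occurrence of each enzyme's recognition sequence on the
#' sense strand; for non-palindromic enzymes the antisense strand is
#' scanned as well (the four default cloning enzymes are palindromic, so
#' both strands are equivalent). Circular input is scanned across the
#' junction.
#'
#' @param s DNA `nt_seq` (linear or circular).
#' @param enzymes [restriction_enzyme()] objects or built-in names.
#' @return data.frame with columns `enzyme`, `start` (0-based),
#'   `strand` (`+`/`-`), `width`, `spans_junction`.
#' @export
find_restriction_sites <- function(s, enzymes) {
  s <- as_nt_seq(s, alphabet = "DNA")
  if (s$alphabet != "DNA")
    stop("find_restriction_sites expects DNA input", call. = FALSE)
  enzymes <- .as_enzyme_list(enzymes)
  L <- length(s)
  circ <- s$topology == "circular"
  w <- if (circ) paste0(s$residues, s$residues) else s$residues
  w_rna <- chartr("T", "U", w)  # reuse RNA pattern matcher
  rows <- list()
  for (e in enzymes) {
    pats <- list(list(pat = e$recognition$residues, strand = "+"))
    if (!is_palindromic(e))
      pats <- c(pats, list(list(
        pat = reverse_complement(e$recognition)$residues, strand = "-")))
    for (pp in pats) {
      starts <- .pattern_starts(chartr("T", "U", pp$pat), w_rna)
      starts <- starts[starts <= L]
      for (c0 in starts) {
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = e$name, start = c0 - 1L, strand = pp$strand,
          width = nchar(pp$pat),
          spans_junction = circ && (c0 - 1L + nchar(pp$pat) > L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(enzyme = character(0), start = integer(0),
                      strand = character(0), width = integer(0),
                      spans_junction = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a binding-site hit table as BED-like TSV
#'
#' Columns: sequence id, start, end (0-based half-open), site class,
#' miRNA id, strand.
#'
#' @param hits data.frame from [find_seed_matches()] or
#'   [find_full_sites()].
#' @param path optional output file.
#' @param seq_id identifier for the scanned sequence.
#' @return The TSV text (invisibly when `path` is given).
#' @export
write_hits_tsv <- function(hits, path = NULL, seq_id = "seq") {
  df <- data.frame(seq_id = rep(seq_id, nrow(hits)),
                   start = hits$start, end = hits$end,
                   site_class = hits$site_class,
                   mirna_id = hits$mirna_id,
                   strand = rep("+", nrow(hits)),
                   stringsAsFactors = FALSE)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}
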