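# Gap-free antiparallel pairing report. The bulged-site geometry keeps
# miRNA and site the same length, so a positional model (no insertions,
# no asymmetric loops) describes the duplex exactly.

#' Positional miRNA:site duplex report
#'
#' Pairs miRNA position p against site position L+1-p (antiparallel,
#' gap-free) and classifies each position as Watson-Crick (`|`), G:U
#' wobble (`o`) or mismatch (`.`). The summary score is
#' `n_wc * w_wc + n_wobble * w_wobble + n_mismatch * w_mismatch`
#' (defaults 1, 0.5, -1).
#'
#' @param m a [mirna()].
#' @param site RNA `nt_seq` or character, same length as the miRNA,
#'   5' to 3' in sponge-transcript sense. A [build_mbs()] result is
#'   accepted directly.
#' @param weights named numeric vector `c(wc=, wobble=, mismatch=)`.
#' @param site_start optional 0-based site coordinate for bookkeeping.
#' @return An object of class `duplex_report`: `pairing` string indexed
#'   by miRNA position 1..L, counts `n_wc`, `n_wobble`, `n_mismatch`,
#'   `mismatch_positions` (miRNA coordinates) and `score`.
#' @examples
#' pair_duplex(mir21(), build_mbs(mir21()))
#' @export
pair_duplex <- function(m, site,
                        weights = c(wc = 1, wobble = 0.5, mismatch = -1),
                        site_start = NA_integer_) {
  stopifnot(inherits(m, "mirna"))
  if (inherits(site, "mbs")) site <- site$seq
  site <- as_nt_seq(site)
  if (site$alphabet != "RNA")
    stop("site must be RNA (transcribe DNA first)", call. = FALSE)
  L <- length(m)
  if (length(site) != L)
    stop("length mismatch: miRNA is ", L, " nt, site is ", length(site),
         " nt (the positional duplex model requires equal lengths)",
         call. = FALSE)
  stopifnot(all(c("wc", "wobble", "mismatch") %in% names(weights)))
  mirc <- .chars(m$seq$residues)
  opp <- rev(.chars(site$residues))  # opp[p] faces miRNA position p
  wc <- .WC[mirc] == opp
  wob <- !wc & .is_wobble(mirc, opp)
  cls <- ifelse(wc, "|", ifelse(wob, "o", "."))
  n_wc <- sum(wc)
  n_wob <- sum(wob)
  n_mm <- L - n_wc - n_wob
  structure(list(
    mirna_id = m$id,
    mirna_seq = m$seq$residues,
    site_seq = site$residues,
    site_start = site_start,
    pairing = paste(cls, collapse = ""),
    n_wc = n_wc, n_wobble = n_wob, n_mismatch = n_mm,
    mismatch_positions = unname(which(cls == ".")),
    score = unname(n_wc * weights["wc"] + n_wob * weights["wobble"] +
                     n_mm * weights["mismatch"])
  ), class = "duplex_report")
}

#' @export
format.duplex_report <- function(x, ...) {
  # site displayed 5'->3'; miRNA (and its per-position pairing string)
  # reversed so column c shows site position c under miRNA position L+1-c
  revstr <- function(s) paste(rev(.chars(s)), collapse = "")
  paste0(
    sprintf("%s duplex: %d WC, %d wobble, %d mismatch (score %g)\n",
            x$mirna_id, x$n_wc, x$n_wobble, x$n_mismatch, x$score),
    sprintf("  miRNA 3'-%s-5'\n", revstr(x$mirna_seq)),
    sprintf("           %s\n", revstr(x$pairing)),
    sprintf("  site  5'-%s-3'\n", x$site_seq))
}

#' @export
print.duplex_report <- function(x, ...) {
  cat(format(x))
  invisible(x)
}

#' Duplex report as JSON
#'
#' @param d a [pair_duplex()] result.
#' @param path optional output file.
#' @return JSON text (invisibly when `path` is given).
#' @export
duplex_json <- function(d, path = NULL) {
  stopifnot(inherits(d, "duplex_report"))
  txt <- jsonlite::toJSON(unclass(d), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
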