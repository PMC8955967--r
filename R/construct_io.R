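# Annotated-record container and flat-file IO. FASTA goes through
# Biostrings; the GenBank flat-file writer/reader is implemented here so
# that designed constructs round-trip (sequence, features, metadata)
# byte-stably.

#' Annotated sequence record
#'
#' A sequence plus an ordered feature table (internal 0-based half-open
#' coordinates) and a key/value metadata snapshot (design parameters,
#' tool version, seed). The unit of GenBank/FASTA IO.
#'
#' @param id record identifier (no whitespace).
#' @param sequence an `nt_seq`.
#' @param features data.frame with columns `name`, `kind`, `start`,
#'   `end` (0-based half-open), or NULL.
#' @param metadata named list of scalar values.
#' @return An object of class `annotated_record`.
#' @export
annotated_record <- function(id, sequence, features = NULL,
                             metadata = list()) {
  stopifnot(inherits(sequence, "nt_seq"))
  id <- as.character(id)
  if (grepl("\\s", id)) stop("record id must not contain whitespace",
                             call. = FALSE)
  if (is.null(features))
    features <- data.frame(name = character(0), kind = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kind", "start", "end") %in% names(features)))
  L <- length(sequence)
  if (nrow(features) &&
      (any(features$start < 0L) || any(features$end > L) ||
       any(features$start >= features$end)))
    stop("feature coordinates out of bounds for a ", L, "-nt sequence",
         call. = FALSE)
  structure(list(id = id, sequence = sequence,
                 features = features[, c("name", "kind", "start", "end")],
                 metadata = metadata),
            class = "annotated_record")
}

#' @export
print.annotated_record <- function(x, ...) {
  cat(sprintf("<annotated_record %s: %d nt %s %s, %d feature(s)>\n",
              x$id, length(x$sequence), x$sequence$alphabet,
              x$sequence$topology, nrow(x$features)))
  invisible(x)
}

.sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]+", "-", x)

.params_metadata <- function(p) {
  list(
    tool = paste0("circsponge-",
                  as.character(utils::packageVersion("circsponge"))),
    n_mbs = p$n_mbs,
    bulge_window = if (is.null(p$bulge_window)) "none"
                   else paste(p$bulge_window, collapse = "-"),
    spacer_len = p$spacer_len,
    flank5 = p$flank5$name,
    flank3 = p$flank3$name,
    forbidden = paste(vapply(p$forbidden_enzymes, `[[`, "", "name"),
                      collapse = ","),
    mismatch_policy = p$mismatch_policy,
    spacer_policy = p$spacer_policy,
    rng_seed = p$rng_seed
  )
}

#' Coerce designed objects to annotated records
#'
#' @param x a `sponge_construct`, `circ_transcript`, `mirna` or `nt_seq`.
#' @param id record identifier; a sensible default is derived from the
#'   object.
#' @param ... unused.
#' @return An [annotated_record()].
#' @export
as_annotated_record <- function(x, ...) UseMethod("as_annotated_record")

#' @rdname as_annotated_record
#' @export
as_annotated_record.sponge_construct <- function(x, id = NULL, ...) {
  if (is.null(id)) id <- paste0(.sanitize_id(x$target), "-sponge")
  annotated_record(id, x$insert, x$features, .params_metadata(x$params))
}

#' @rdname as_annotated_record
#' @export
as_annotated_record.circ_transcript <- function(x, id = NULL, ...) {
  if (is.null(id)) id <- paste0(.sanitize_id(x$origin), "-circ")
  annotated_record(id, x$seq, x$features,
                   list(junction_offset = x$junction_offset))
}

#' @rdname as_annotated_record
#' @export
as_annotated_record.mirna <- function(x, id = NULL, ...) {
  if (is.null(id)) id <- .sanitize_id(x$id)
  annotated_record(id, x$seq,
                   metadata = list(seed_range = paste(x$seed_range,
                                                      collapse = "-")))
}

#' @rdname as_annotated_record
#' @export
as_annotated_record.nt_seq <- function(x, id = "seq", ...) {
  annotated_record(id, x)
}

#' @rdname as_annotated_record
#' @export
as_annotated_record.annotated_record <- function(x, ...) x

## ---- GenBank flat file ----------------------------------------------

#' Write an annotated record as a GenBank flat file
#'
#' Emits a GenBank record with 1-based inclusive feature locations
#' (`misc_feature` entries labelled as in the feature table: flank5,
#' MBS1..MBSn, spacer1.., flank3), the molecule type and topology on
#' the LOCUS line ("DNA linear" for inserts, "RNA circular" for
#' back-spliced transcripts) and the metadata snapshot in COMMENT
#' lines. `read_genbank(write_genbank(r))` reproduces the sequence,
#' feature table and metadata exactly.
#'
#' @param r an [annotated_record()] (or an object coercible via
#'   [as_annotated_record()]).
#' @param path optional output file.
#' @return GenBank text (invisibly when `path` is given).
#' @export
write_genbank <- function(r, path = NULL) {
  r <- as_annotated_record(r)
  s <- r$sequence
  L <- length(s)
  lines <- character(0)
  lines <- c(lines, sprintf("LOCUS       %-16s %d bp    %s     %-8s SYN 01-JAN-1980",
                            r$id, L, s$alphabet, s$topology))
  lines <- c(lines, sprintf("DEFINITION  %s.", r$id),
             "ACCESSION   .",
             "VERSION     .",
             "KEYWORDS    .",
             "SOURCE      synthetic construct",
             "  ORGANISM  synthetic construct")
  for (k in names(r$metadata))
    lines <- c(lines, sprintf("COMMENT     circsponge_meta: %s=%s", k,
                              as.character(r$metadata[[k]])))
  lines <- c(lines, "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(r$features))) {
    f <- r$features[i, ]
    lines <- c(lines,
               sprintf("     misc_feature    %d..%d", f$start + 1L, f$end),
               sprintf("                     /label=\"%s\"", f$name),
               sprintf("                     /note=\"kind=%s\"", f$kind))
  }
  lines <- c(lines, "ORIGIN")
  res <- tolower(s$residues)
  pos <- seq(1L, L, by = 60L)
  for (p0 in pos) {
    chunk <- substr(res, p0, min(p0 + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L,
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p0, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

.gb_fail <- function(lineno, msg) {
  stop(sprintf("GenBank parse error at line %d: %s", lineno, msg),
       call. = FALSE)
}

#' Read a GenBank flat file
#'
#' Parses a single-record GenBank flat file as written by
#' [write_genbank()]: LOCUS name/length/moltype/topology,
#' `misc_feature` locations with `/label` and `/note="kind=..."`
#' qualifiers, `COMMENT circsponge_meta:` metadata and the ORIGIN
#' sequence. Malformed input raises an error naming the offending line.
#'
#' @param input path to a GenBank file, or the flat-file text itself.
#' @return An [annotated_record()].
#' @export
read_genbank <- function(input) {
  lines <- .input_lines(input)
  if (!length(lines)) stop("empty GenBank input", call. = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) .gb_fail(1L, "missing LOCUS line")
  toks <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  if (length(toks) < 6L || toks[4] != "bp")
    .gb_fail(locus_i[1], "malformed LOCUS line")
  id <- toks[2]
  declared_len <- suppressWarnings(as.integer(toks[3]))
  if (is.na(declared_len)) .gb_fail(locus_i[1], "bad sequence length")
  alphabet <- toks[5]
  topology <- toks[6]
  if (!alphabet %in% c("DNA", "RNA"))
    .gb_fail(locus_i[1], paste0("unsupported molecule type '", alphabet, "'"))
  if (!topology %in% c("linear", "circular"))
    .gb_fail(locus_i[1], paste0("unsupported topology '", topology, "'"))

  metadata <- list()
  for (i in grep("^COMMENT\\s+circsponge_meta:", lines)) {
    kv <- sub("^COMMENT\\s+circsponge_meta:\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1L) .gb_fail(i, "metadata line lacks '='")
    metadata[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }

  feats <- list()
  in_features <- FALSE
  cur <- NULL
  flush <- function() {
    if (!is.null(cur))
      feats[[length(feats) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^FEATURES", ln)) { in_features <- TRUE; next }
    if (grepl("^ORIGIN", ln)) { flush(); in_features <- FALSE; next }
    if (!in_features) next
    if (grepl("^     \\S", ln)) {
      flush()
      key <- sub("^\\s+", "", substr(ln, 1L, 20L))
      key <- sub("\\s+$", "", key)
      loc <- trimws(substr(ln, 21L, nchar(ln)))
      if (key == "source") next
      if (key != "misc_feature") .gb_fail(i, paste0("unsupported feature key '", key, "'"))
      mt <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
      if (length(mt) != 3L) .gb_fail(i, paste0("unsupported location '", loc, "'"))
      cur <- list(name = NA_character_, kind = "misc_feature",
                  start = as.integer(mt[2]) - 1L, end = as.integer(mt[3]))
    } else if (grepl("^\\s+/", ln)) {
      if (is.null(cur)) .gb_fail(i, "qualifier outside a feature")
      q <- trimws(ln)
      if (grepl('^/label="', q))
        cur$name <- sub('^/label="(.*)"$', "\\1", q)
      else if (grepl('^/note="kind=', q))
        cur$kind <- sub('^/note="kind=(.*)"$', "\\1", q)
    }
  }

  origin_i <- grep("^ORIGIN", lines)
  seq_txt <- ""
  if (length(origin_i)) {
    j <- origin_i[1] + 1L
    while (j <= length(lines) && !grepl("^//", lines[j])) {
      body <- gsub("[\\s0-9]", "", lines[j], perl = TRUE)
      if (!grepl("^[acgtuACGTU]*$", body))
        .gb_fail(j, "non-nucleotide characters in ORIGIN block")
      seq_txt <- paste0(seq_txt, body)
      j <- j + 1L
    }
    if (j > length(lines)) .gb_fail(length(lines), "missing '//' terminator")
  }
  if (nchar(seq_txt) != declared_len)
    .gb_fail(locus_i[1], sprintf("LOCUS declares %d bp but ORIGIN holds %d",
                                 declared_len, nchar(seq_txt)))
  features <- if (length(feats)) {
    data.frame(name = vapply(feats, `[[`, "", "name"),
               kind = vapply(feats, `[[`, "", "kind"),
               start = vapply(feats, `[[`, 0L, "start"),
               end = vapply(feats, `[[`, 0L, "end"),
               stringsAsFactors = FALSE)
  } else NULL
  annotated_record(id, nt_seq(toupper(seq_txt), alphabet, topology),
                   features, metadata)
}

## ---- FASTA -----------------------------------------------------------

.input_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input)
  else unlist(strsplit(paste(input, collapse = "\n"), "\n"))
}

.record_header <- function(r) {
  desc <- character(0)
  if (r$sequence$topology == "circular") desc <- c(desc, "topology=circular")
  if (length(desc)) paste(r$id, paste(desc, collapse = " "))
  else r$id
}

#' Write records as FASTA
#'
#' Standard FASTA with 60-column wrapping (via Biostrings). Circular
#' sequences carry `topology=circular` in the description line;
#' `doubled_circular = TRUE` additionally emits each circular sequence
#' doubled (id suffix `_doubled`) for tools without circular support.
#'
#' @param records a record or list of records ([annotated_record()],
#'   `nt_seq`, `mirna`, `sponge_construct`, `circ_transcript`).
#' @param path optional output file.
#' @param doubled_circular also write doubled copies of circular
#'   sequences.
#' @return FASTA text (invisibly when `path` is given).
#' @export
write_fasta <- function(records, path = NULL, doubled_circular = FALSE) {
  if (!is.list(records) || inherits(records, c("annotated_record", "nt_seq",
                                               "mirna", "sponge_construct",
                                               "circ_transcript")))
    records <- list(records)
  records <- lapply(records, as_annotated_record)
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  headers <- vapply(records, .record_header, "")
  seqs <- vapply(records, function(r) r$sequence$residues, "")
  if (doubled_circular) {
    circ <- vapply(records, function(r) r$sequence$topology == "circular",
                   TRUE)
    headers <- c(headers, paste0(ids[circ], "_doubled doubled circular"))
    seqs <- c(seqs, paste0(seqs[circ], seqs[circ]))
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  out <- if (is.null(path)) tempfile(fileext = ".fasta") else path
  Biostrings::writeXStringSet(set, out, width = 60L)
  txt <- paste0(paste(readLines(out), collapse = "\n"), "\n")
  if (is.null(path)) {
    unlink(out)
    return(txt)
  }
  invisible(txt)
}

#' Read FASTA records
#'
#' Reads a miRBase-style FASTA file (or text) via Biostrings. The
#' alphabet of each record is inferred from its residues (U implies
#' RNA, T implies DNA, neither defaults to RNA) and a
#' `topology=circular` token in the description marks circular
#' sequences.
#'
#' @param input path or FASTA text; empty input yields an empty list.
#' @return List of [annotated_record()]s.
#' @export
read_fasta <- function(input) {
  lines <- .input_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !any(grepl("^>", lines))) return(list())
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  set <- Biostrings::readBStringSet(tmp)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lapply(seq_along(set), function(i) {
    res <- toupper(as.character(set[[i]]))
    topo <- if (grepl("topology=circular", headers[i], fixed = TRUE))
      "circular" else "linear"
    annotated_record(ids[i], as_nt_seq(res, topology = topo))
  })
}

#' Read a miRNA panel from FASTA
#'
#' Convenience wrapper over [read_fasta()] that returns [mirna()]
#' objects; DNA-alphabet entries are transcribed to RNA.
#'
#' @param input path or FASTA text.
#' @param seed_range seed range applied to every miRNA.
#' @return List of [mirna()].
#' @export
read_mirna_fasta <- function(input, seed_range = c(2L, 8L)) {
  recs <- read_fasta(input)
  lapply(recs, function(r) {
    s <- r$sequence
    if (s$alphabet == "DNA") s <- transcribe(s)
    mirna(r$id, s, seed_range = seed_range)
  })
}
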