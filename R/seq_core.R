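#' @keywords internal
"_PACKAGE"

NT_RNA <- c("A", "C", "G", "U")
NT_DNA <- c("A", "C", "G", "T")

# Watson-Crick partner of each RNA base; G:U / U:G wobble handled separately.
.WC <- c(A = "U", C = "G", G = "C", U = "A")

.is_wobble <- function(x, y) (x == "G" & y == "U") | (x == "U" & y == "G")

# run expr with a fixed RNG seed, restoring global RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validated nucleotide sequence
#'
#' The elementary container of the package: a nucleotide string with a
#' declared alphabet (RNA or DNA) and topology (linear or circular).
#' Residues are upper-cased on construction; ambiguity codes (N, R, Y, ...)
#' are rejected because the sponge design procedure is undefined for
#' ambiguous bases. Circular sequences compare equal to any rotation of
#' themselves (see [canonical_rotation()]).
#'
#' Linear sequences may be empty (a zero-length spacer is a legitimate
#' design choice); circular sequences must contain at least one residue.
#'
#' @param residues single character string over A/C/G/U (RNA) or A/C/G/T
#'   (DNA); lowercase accepted.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `nt_seq`.
#' @examples
#' rna("UAGCUUAUCAGACUGAUGUUGA")
#' dna("gatatc")
#' rna("AUGC", topology = "circular") == rna("GCAU", topology = "circular")
#' @export
nt_seq <- function(residues, alphabet = c("RNA", "DNA"),
                   topology = c("linear", "circular")) {
  alphabet <- match.arg(alphabet)
  topology <- match.arg(topology)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("residues must be a single character string", call. = FALSE)
  res <- toupper(residues)
  pat <- if (alphabet == "RNA") "^[ACGU]*$" else "^[ACGT]*$"
  if (!grepl(pat, res))
    stop(sprintf(
      "invalid %s sequence: residues outside {%s} (ambiguity codes are not supported)",
      alphabet,
      paste(if (alphabet == "RNA") NT_RNA else NT_DNA, collapse = ",")),
      call. = FALSE)
  if (nchar(res) == 0L && topology == "circular")
    stop("a circular sequence must be non-empty", call. = FALSE)
  structure(list(residues = res, alphabet = alphabet, topology = topology),
            class = "nt_seq")
}

#' @rdname nt_seq
#' @export
rna <- function(residues, topology = "linear") nt_seq(residues, "RNA", topology)

#' @rdname nt_seq
#' @export
dna <- function(residues, topology = "linear") nt_seq(residues, "DNA", topology)

#' Coerce to a nucleotide sequence
#'
#' Character input has its alphabet inferred from its residues: a `U`
#' implies RNA, a `T` implies DNA; strings containing neither default to
#' RNA (overridable via `alphabet`).
#'
#' @param x `nt_seq` or character scalar.
#' @param alphabet alphabet to assume when it cannot be inferred.
#' @param topology topology for character input.
#' @return An `nt_seq`.
#' @export
as_nt_seq <- function(x, alphabet = NULL, topology = "linear") {
  if (inherits(x, "nt_seq")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("cannot coerce to nt_seq: expected nt_seq or character scalar",
         call. = FALSE)
  up <- toupper(x)
  alpha <- if (grepl("U", up, fixed = TRUE)) "RNA"
    else if (grepl("T", up, fixed = TRUE)) "DNA"
    else if (!is.null(alphabet)) alphabet else "RNA"
  nt_seq(x, alpha, topology)
}

#' @export
length.nt_seq <- function(x) nchar(x$residues)

#' @export
as.character.nt_seq <- function(x, ...) x$residues

#' @export
print.nt_seq <- function(x, ...) {
  res <- x$residues
  shown <- if (nchar(res) > 70) paste0(substr(res, 1, 67), "...") else res
  cat(sprintf("<nt_seq %s %s, %d nt>\n%s\n", x$alphabet, x$topology,
              nchar(res), shown))
  invisible(x)
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically minimal rotation, the canonical
#' representative used for circular equality. Linear sequences are
#' returned unchanged.
#'
#' @param s an `nt_seq`.
#' @return An `nt_seq` with the same alphabet and topology.
#' @export
canonical_rotation <- function(s) {
  stopifnot(inherits(s, "nt_seq"))
  if (s$topology != "circular") return(s)
  r <- s$residues
  L <- nchar(r)
  if (L == 1L) return(s)
  dd <- paste0(r, r)
  rots <- substring(dd, seq_len(L), seq_len(L) + L - 1L)
  nt_seq(min(rots), s$alphabet, "circular")
}

#' @export
Ops.nt_seq <- function(e1, e2) {
  if (!.Generic %in% c("==", "!="))
    stop("operation '", .Generic, "' is not defined for nt_seq objects",
         call. = FALSE)
  eq <- inherits(e1, "nt_seq") && inherits(e2, "nt_seq") &&
    e1$alphabet == e2$alphabet && e1$topology == e2$topology &&
    (if (e1$topology == "circular")
       canonical_rotation(e1)$residues == canonical_rotation(e2)$residues
     else e1$residues == e2$residues)
  if (.Generic == "==") eq else !eq
}

#' Reverse complement
#'
#' Complements every base in the declared alphabet and reverses the
#' string; alphabet, topology and length are preserved. An involution:
#' applying it twice returns the input.
#'
#' @param s an `nt_seq` (or character, coerced via [as_nt_seq()]).
#' @return An `nt_seq`.
#' @examples
#' as.character(reverse_complement(rna("UAGCUUAUCAGACUGAUGUUGA")))
#' @export
reverse_complement <- function(s) {
  s <- as_nt_seq(s)
  comp <- if (s$alphabet == "RNA") chartr("ACGU", "UGCA", s$residues)
          else chartr("ACGT", "TGCA", s$residues)
  rev_str <- paste(rev(.chars(comp)), collapse = "")
  nt_seq(rev_str, s$alphabet, s$topology)
}

#' Transcribe DNA to RNA / back-transcribe RNA to DNA
#'
#' Sense-strand transcription is modelled as the T/U letter substitution
#' only; length and topology are preserved. The two maps are mutually
#' inverse.
#'
#' @param s an `nt_seq` of the appropriate alphabet.
#' @return An `nt_seq` of the other alphabet.
#' @export
transcribe <- function(s) {
  stopifnot(inherits(s, "nt_seq"))
  if (s$alphabet != "DNA")
    stop("transcribe expects a DNA sequence", call. = FALSE)
  nt_seq(chartr("T", "U", s$residues), "RNA", s$topology)
}

#' @rdname transcribe
#' @export
back_transcribe <- function(s) {
  stopifnot(inherits(s, "nt_seq"))
  if (s$alphabet != "RNA")
    stop("back_transcribe expects an RNA sequence", call. = FALSE)
  nt_seq(chartr("U", "T", s$residues), "DNA", s$topology)
}

#' A microRNA with its seed region
#'
#' Bundles a miRBase-style identifier with a linear 5'-to-3' RNA sequence
#' and the 1-based inclusive seed range (default positions 2-8, the
#' primary determinant of target recognition). Sequences shorter than
#' 15 nt are rejected as not miRNA-like.
#'
#' @param id identifier, e.g. `"hsa-miR-21-5p"`.
#' @param seq RNA `nt_seq` or character string (T is not accepted).
#' @param seed_range length-2 integer vector, 1-based inclusive.
#' @return An object of class `mirna`.
#' @examples
#' m <- mirna("hsa-miR-21-5p", "UAGCUUAUCAGACUGAUGUUGA")
#' as.character(seed_of(m))
#' @export
mirna <- function(id, seq, seed_range = c(2L, 8L)) {
  if (is.character(seq)) seq <- rna(seq)
  stopifnot(inherits(seq, "nt_seq"))
  if (seq$alphabet != "RNA") stop("miRNA sequence must be RNA", call. = FALSE)
  if (seq$topology != "linear")
    stop("miRNA sequence must be linear", call. = FALSE)
  L <- nchar(seq$residues)
  if (L < 15L)
    stop("miRNA-like sequence expected (length >= 15), got ", L, " nt",
         call. = FALSE)
  seed_range <- as.integer(seed_range)
  if (length(seed_range) != 2L || any(is.na(seed_range)) ||
      seed_range[1] < 1L || seed_range[2] > L || seed_range[1] > seed_range[2])
    stop("seed_range must lie within [1, ", L, "]", call. = FALSE)
  structure(list(id = as.character(id), seq = seq, seed_range = seed_range),
            class = "mirna")
}

#' @export
length.mirna <- function(x) nchar(x$seq$residues)

#' @export
print.mirna <- function(x, ...) {
  cat(sprintf("<mirna %s, %d nt, seed %d-%d>\n5'-%s-3'\n", x$id,
              length(x), x$seed_range[1], x$seed_range[2], x$seq$residues))
  invisible(x)
}

#' Seed subsequence of a miRNA
#'
#' @param m a [mirna()].
#' @return Linear RNA `nt_seq` covering `seed_range` (default 2-8, 7 nt).
#' @export
seed_of <- function(m) {
  stopifnot(inherits(m, "mirna"))
  rna(substr(m$seq$residues, m$seed_range[1], m$seed_range[2]))
}

#' The hsa-miR-21-5p reference miRNA
#'
#' The worked example throughout the package: the mature miR-21-5p guide
#' (miRBase accession MIMAT0000076), 22 nt, seed positions 2-8.
#'
#' @return A [mirna()] object.
#' @export
mir21 <- function() mirna("hsa-miR-21-5p", "UAGCUUAUCAGACUGAUGUUGA")
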