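# Sequence-level back-splicing model. The circularized region is exactly
# the insert between the vector's ALU arms: the ALU arms, CMV promoter and
# EGFP reporter lie outside the circle and are not modelled as sequence.
# The flanking restriction-site bases are retained inside the circle.

#' Back-splice a sponge construct
#'
#' Derives the circular sponge transcript from a DNA insert: the insert
#' is transcribed and covalently closed, joining the insert's 3' end
#' back to its 5' start. The canonical rotation starts at the first base
#' of the 5' flank (junction offset 0), giving stable human-readable
#' coordinates shared with the linear insert.
#'
#' @param construct a [assemble_insert()] result.
#' @return An object of class `circ_transcript`: circular RNA `seq`,
#'   `origin` (target miRNA id), `junction_offset`, and the construct's
#'   feature table.
#' @examples
#' tx <- backsplice(assemble_insert(mir21()))
#' length(tx$seq)
#' @export
backsplice <- function(construct) {
  stopifnot(inherits(construct, "sponge_construct"))
  if (length(construct$insert) == 0L)
    stop("cannot back-splice an empty insert", call. = FALSE)
  structure(list(
    seq = nt_seq(chartr("T", "U", construct$insert$residues),
                 "RNA", "circular"),
    origin = construct$target,
    junction_offset = 0L,
    features = construct$features
  ), class = "circ_transcript")
}

#' @export
print.circ_transcript <- function(x, ...) {
  cat(sprintf("<circ_transcript from %s sponge: %d nt circular RNA, junction at %d>\n",
              x$origin, length(x$seq), x$junction_offset))
  invisible(x)
}

#' @export
length.circ_transcript <- function(x) length(x$seq)

#' Rotate a circular sequence
#'
#' Moves the origin forward by `k` positions (mod length). The result
#' is equal to the input under circular equality.
#'
#' @param s circular `nt_seq`.
#' @param k integer rotation.
#' @return A circular `nt_seq`.
#' @export
rotate <- function(s, k) {
  stopifnot(inherits(s, "nt_seq"))
  if (s$topology != "circular")
    stop("rotate requires a circular sequence", call. = FALSE)
  L <- length(s)
  k <- as.integer(k %% L)
  if (k == 0L) return(s)
  r <- s$residues
  nt_seq(paste0(substr(r, k + 1L, L), substr(r, 1L, k)),
         s$alphabet, "circular")
}

#' Linearize a circular transcript
#'
#' Opens the circle at an offset (default the back-splice junction),
#' returning the linear RNA read 5' to 3' from that point. Linearizing
#' at the junction recovers the transcribed insert exactly.
#'
#' @param tx a [backsplice()] result.
#' @param at 0-based offset at which to open the circle.
#' @return A linear RNA `nt_seq`.
#' @export
linearize <- function(tx, at = tx$junction_offset) {
  stopifnot(inherits(tx, "circ_transcript"))
  opened <- rotate(tx$seq, at)
  nt_seq(opened$residues, "RNA", "linear")
}

#' Junction-spanning window
#'
#' Returns the `2w`-nt linear sequence centred on the back-splice
#' junction: the last `w` bases of the canonical rotation joined to its
#' first `w` bases. This is the region a junction-spanning divergent
#' RT-PCR primer pair would amplify, and is unique to the circular
#' (never the linear) transcript.
#'
#' @param tx a [backsplice()] result.
#' @param w half-window width in nt; `2 * w` must not exceed the
#'   transcript length.
#' @return A linear RNA `nt_seq` of length `2 * w`.
#' @examples
#' as.character(junction_window(backsplice(assemble_insert(mir21())), 6))
#' @export
junction_window <- function(tx, w) {
  stopifnot(inherits(tx, "circ_transcript"))
  w <- as.integer(w)
  L <- length(tx$seq)
  if (is.na(w) || w < 1L) stop("w must be a positive integer", call. = FALSE)
  if (2L * w > L)
    stop("window 2*", w, " exceeds transcript length ", L, call. = FALSE)
  r <- tx$seq$residues
  rna(paste0(substr(r, L - w + 1L, L), substr(r, 1L, w)))
}
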