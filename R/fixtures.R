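# Seeded generators of synthetic miRNAs and decoy panels for off-target
# checks, tests and demos. Everything here is reproducible: the same
# seed always yields the same panel.

.draw_mirna_seq <- function(len_range, gc_range, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    L <- sample(seq(len_range[1], len_range[2]), 1L)
    res <- sample(NT_RNA, L, replace = TRUE)
    gc <- mean(res %in% c("G", "C"))
    if (gc >= gc_range[1] && gc <= gc_range[2])
      return(paste(res, collapse = ""))
  }
  stop("could not draw a sequence inside the GC range after ",
       max_attempts, " attempts", call. = FALSE)
}

#' Draw a random synthetic miRNA
#'
#' Uniform random RNA within a length and GC-content range, wrapped as
#' a [mirna()]. Uses the current RNG state; wrap in a seeded context
#' (or use [generate_decoy_panel()]) for reproducibility.
#'
#' @param id identifier for the synthetic miRNA.
#' @param len_range inclusive length range in nt.
#' @param gc_range inclusive GC-fraction range.
#' @return A [mirna()].
#' @export
random_mirna <- function(id = "synthetic-mir", len_range = c(20L, 24L),
                         gc_range = c(0.3, 0.7)) {
  mirna(id, .draw_mirna_seq(len_range, gc_range))
}

#' Generate a seeded decoy miRNA panel
#'
#' Draws `n` synthetic miRNAs by rejection sampling, excluding any
#' candidate whose 6mer seed (positions 2-7) equals the target's, so no
#' decoy can recognise the target's own binding sites. Optionally a
#' `screen` sequence (e.g. the designed sponge transcript) is scanned
#' and candidates with any seed match on it are rejected too, yielding
#' a panel guaranteed clean for off-target validation. Deterministic
#' per seed.
#'
#' @param target the target [mirna()].
#' @param n panel size (0 yields an empty list).
#' @param rng_seed integer seed.
#' @param len_range,gc_range as in [random_mirna()].
#' @param screen optional `nt_seq` the decoys must not seed-match.
#' @param max_attempts total rejection budget.
#' @return List of `n` [mirna()] objects named `decoy-1` ...
#' @examples
#' panel <- generate_decoy_panel(mir21(), n = 3, rng_seed = 42)
#' vapply(panel, `[[`, "", "id")
#' @export
generate_decoy_panel <- function(target, n = 20L, rng_seed = 42L,
                                 len_range = c(20L, 24L),
                                 gc_range = c(0.3, 0.7),
                                 screen = NULL,
                                 max_attempts = 1000L * max(1L, n)) {
  stopifnot(inherits(target, "mirna"))
  n <- as.integer(n)
  if (n == 0L) return(list())
  target_seed6 <- substr(target$seq$residues, 2L, 7L)
  .with_seed(rng_seed, {
    panel <- list()
    attempts <- 0L
    while (length(panel) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("decoy rejection budget exhausted after ", max_attempts,
             " attempts; relax the screen or change the seed",
             call. = FALSE)
      cand <- mirna(paste0("decoy-", length(panel) + 1L),
                    .draw_mirna_seq(len_range, gc_range))
      if (substr(cand$seq$residues, 2L, 7L) == target_seed6) next
      if (!is.null(screen) &&
          nrow(find_seed_matches(screen, cand)) > 0L) next
      panel[[length(panel) + 1L]] <- cand
    }
    names(panel) <- vapply(panel, `[[`, "", "id")
    panel
  })
}
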