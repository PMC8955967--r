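# Recognition sequences are the canonical enzyme-table constants; all four
# defaults are palindromic, so sense-strand scanning covers both strands.
.ENZYME_TABLE <- c(
  EcoRV   = "GATATC",
  SacII   = "CCGCGG",
  HindIII = "AAGCTT",
  EcoRI   = "GAATTC"
)

#' Restriction endonuclease
#'
#' A named enzyme with its double-stranded DNA recognition sequence.
#' The four enzymes used by the default sponge design (EcoRV, SacII,
#' HindIII, EcoRI) are built in and can be requested by name alone.
#'
#' @param name enzyme name.
#' @param recognition DNA recognition sequence (`nt_seq` or character);
#'   may be omitted for built-in enzymes. Must be at least 4 bp.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("EcoRV")
#' restriction_enzyme("BamHI", "GGATCC")
#' @export
restriction_enzyme <- function(name, recognition = NULL) {
  if (inherits(name, "restriction_enzyme")) return(name)
  name <- as.character(name)
  if (is.null(recognition)) {
    rec <- unname(.ENZYME_TABLE[name])
    if (is.na(rec))
      stop("unknown enzyme '", name,
           "': supply its recognition sequence explicitly", call. = FALSE)
  } else {
    rec <- if (inherits(recognition, "nt_seq")) recognition$residues
           else toupper(as.character(recognition))
  }
  rec <- dna(rec)
  if (length(rec) < 4L)
    stop("recognition sequence must be at least 4 bp", call. = FALSE)
  structure(list(name = name, recognition = rec),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme %s: %s%s>\n", x$name,
              x$recognition$residues,
              if (is_palindromic(x)) " (palindromic)" else ""))
  invisible(x)
}

#' Is a recognition sequence palindromic?
#'
#' TRUE when the recognition site equals its own reverse complement, in
#' which case a sense-strand scan finds all double-stranded occurrences.
#'
#' @param e a [restriction_enzyme()].
#' @export
is_palindromic <- function(e) {
  stopifnot(inherits(e, "restriction_enzyme"))
  reverse_complement(e$recognition)$residues == e$recognition$residues
}

.as_enzyme_list <- function(x) {
  if (inherits(x, "restriction_enzyme")) x <- list(x)
  lapply(x, restriction_enzyme)
}

#' Sponge design parameters
#'
#' All tunables of the sponge construction procedure. Defaults encode
#' the reference design: 7 tandem miRNA binding sites (MBS), a central
#' bulge mispairing miRNA positions 10-13, 4-nt spacers between
#' consecutive MBS, EcoRV/SacII flanks for directional cloning, and the
#' cloning enzymes (EcoRV, SacII, HindIII, EcoRI) forbidden anywhere
#' inside the insert.
#'
#' The bulge window is expressed in *miRNA* coordinates (1-based): the
#' bulge blocks the catalytic centre of AGO2-loaded miRNA, so it is
#' positioned relative to the guide. For a 22-nt miRNA, MBS positions
#' 10-13 oppose miRNA positions 10-13 under antiparallel pairing, so
#' the two coordinate readings coincide for the reference design.
#' `bulge_window = NULL` requests a degenerate (width-0) bulge, i.e. a
#' perfectly complementary site.
#'
#' @param n_mbs number of binding sites (>= 1).
#' @param bulge_window 1-based inclusive miRNA-position pair, or NULL.
#' @param spacer_len spacer length in nt (>= 0).
#' @param flank5,flank3 [restriction_enzyme()] (or built-in name) whose
#'   recognition sequence is appended to the 5'/3' insert end.
#' @param forbidden_enzymes enzymes whose recognition sequences must not
#'   occur inside the insert (terminal flank copies exempted).
#' @param mismatch_policy `"identity"` places the miRNA's own base
#'   opposite itself at each bulge position (non-pairing for all four
#'   bases, fully deterministic); `"seeded_random"` draws uniformly from
#'   the bases that neither Watson-Crick- nor wobble-pair.
#' @param spacer_policy `"seeded_search"` runs an independent seeded
#'   constraint search per inter-MBS gap; `"fixed"` reuses the first
#'   gap's spacer for every gap.
#' @param rng_seed integer seed driving every stochastic choice.
#' @return An object of class `design_params`.
#' @export
design_params <- function(n_mbs = 7L,
                          bulge_window = c(10L, 13L),
                          spacer_len = 4L,
                          flank5 = "EcoRV",
                          flank3 = "SacII",
                          forbidden_enzymes = c("EcoRV", "SacII",
                                                "HindIII", "EcoRI"),
                          mismatch_policy = c("identity", "seeded_random"),
                          spacer_policy = c("seeded_search", "fixed"),
                          rng_seed = 1L) {
  mismatch_policy <- match.arg(mismatch_policy)
  spacer_policy <- match.arg(spacer_policy)
  n_mbs <- as.integer(n_mbs)
  spacer_len <- as.integer(spacer_len)
  if (is.na(n_mbs) || n_mbs < 1L) stop("n_mbs must be >= 1", call. = FALSE)
  if (is.na(spacer_len) || spacer_len < 0L)
    stop("spacer_len must be >= 0", call. = FALSE)
  if (!is.null(bulge_window)) {
    bulge_window <- as.integer(bulge_window)
    if (length(bulge_window) != 2L || any(is.na(bulge_window)) ||
        bulge_window[1] < 1L || bulge_window[1] > bulge_window[2])
      stop("bulge_window must be an increasing 1-based position pair or NULL",
           call. = FALSE)
  }
  structure(list(
    n_mbs = n_mbs,
    bulge_window = bulge_window,
    spacer_len = spacer_len,
    flank5 = restriction_enzyme(flank5),
    flank3 = restriction_enzyme(flank3),
    forbidden_enzymes = .as_enzyme_list(forbidden_enzymes),
    mismatch_policy = mismatch_policy,
    spacer_policy = spacer_policy,
    rng_seed = as.integer(rng_seed)
  ), class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  bw <- if (is.null(x$bulge_window)) "none (perfect sites)"
        else paste(x$bulge_window, collapse = "-")
  cat("<design_params>\n")
  cat(sprintf("  n_mbs: %d   bulge window (miRNA pos): %s   spacer: %d nt\n",
              x$n_mbs, bw, x$spacer_len))
  cat(sprintf("  flanks: %s (%s) / %s (%s)\n",
              x$flank5$name, x$flank5$recognition$residues,
              x$flank3$name, x$flank3$recognition$residues))
  cat(sprintf("  forbidden: %s\n",
              paste(vapply(x$forbidden_enzymes, `[[`, "", "name"),
                    collapse = ", ")))
  cat(sprintf("  mismatch policy: %s   spacer policy: %s   seed: %d\n",
              x$mismatch_policy, x$spacer_policy, x$rng_seed))
  invisible(x)
}

.bulge_width <- function(p) {
  if (is.null(p$bulge_window)) 0L
  else p$bulge_window[2] - p$bulge_window[1] + 1L
}

.validate_design <- function(m, p) {
  stopifnot(inherits(m, "mirna"), inherits(p, "design_params"))
  if (is.null(p$bulge_window)) return(invisible(TRUE))
  L <- length(m)
  bw <- p$bulge_window
  if (bw[2] > L)
    stop("bulge window ", bw[1], "-", bw[2],
         " lies outside the ", L, "-nt miRNA", call. = FALSE)
  sr <- m$seed_range
  if (bw[1] <= sr[2] && sr[1] <= bw[2])
    stop("bulge window ", bw[1], "-", bw[2],
         " overlaps the seed region ", sr[1], "-", sr[2],
         ": a bulged site must keep the seed perfectly paired",
         call. = FALSE)
  invisible(TRUE)
}

# bases that neither WC- nor wobble-pair with miRNA base x
.nonpairing_bases <- function(x) {
  excl <- .WC[[x]]
  if (x == "G") excl <- c(excl, "U")
  if (x == "U") excl <- c(excl, "G")
  setdiff(NT_RNA, excl)
}

#' Build one bulged miRNA binding site
#'
#' Constructs a single MBS: the reverse complement of the miRNA with the
#' bases opposite the bulge window replaced by non-pairing bases, so
#' that the site pairs perfectly everywhere except a central bulge that
#' prevents AGO2-mediated slicing of the sponge. With the default
#' `identity` policy the bulge base opposite miRNA base X is X itself
#' (A:A, C:C, G:G, U:U are neither Watson-Crick nor wobble pairs), which
#' makes the design deterministic without an RNG.
#'
#' @param m target [mirna()].
#' @param p [design_params()].
#' @return An object of class `mbs`: sponge-sense RNA site (`seq`),
#'   1-based bulge positions in MBS coordinates (`bulge_positions_mbs`),
#'   the miRNA-coordinate window (`bulge_window_mirna`) and the source
#'   miRNA id.
#' @examples
#' as.character(build_mbs(mir21(), design_params())$seq)
#' @export
build_mbs <- function(m, p = design_params()) {
  .validate_design(m, p)
  L <- length(m)
  site <- .chars(reverse_complement(m$seq)$residues)
  mirc <- .chars(m$seq$residues)
  width <- .bulge_width(p)
  mbs_pos <- integer(0)
  if (width > 0L) {
    qs <- seq(p$bulge_window[1], p$bulge_window[2])
    mbs_pos <- L + 1L - qs
    if (p$mismatch_policy == "identity") {
      site[mbs_pos] <- mirc[qs]
    } else {
      picks <- .with_seed(p$rng_seed, vapply(mirc[qs], function(b) {
        cand <- .nonpairing_bases(b)
        cand[sample.int(length(cand), 1L)]
      }, ""))
      site[mbs_pos] <- picks
    }
  }
  structure(list(
    seq = rna(paste(site, collapse = "")),
    bulge_positions_mbs = sort(mbs_pos),
    bulge_window_mirna = p$bulge_window,
    source_mirna = m$id
  ), class = "mbs")
}

#' @export
print.mbs <- function(x, ...) {
  cat(sprintf("<mbs for %s, %d nt, bulge at MBS positions %s>\n5'-%s-3'\n",
              x$source_mirna, length(x$seq),
              if (length(x$bulge_positions_mbs))
                paste(range(x$bulge_positions_mbs), collapse = "-")
              else "none",
              x$seq$residues))
  invisible(x)
}

.overlaps <- function(start, end, lo, hi) start < hi & end > lo

# does candidate spacer, in context, create a target seed match or a
# forbidden restriction site overlapping the spacer interval?
.spacer_ok <- function(cand, left, right, target, p) {
  join <- paste0(left, cand, right)
  lo <- nchar(left)
  hi <- lo + nchar(cand)
  seed_hits <- find_seed_matches(rna(join), target)
  if (nrow(seed_hits) &&
      any(.overlaps(seed_hits$start, seed_hits$end, lo, hi)))
    return(FALSE)
  rs <- find_restriction_sites(back_transcribe(rna(join)),
                               p$forbidden_enzymes)
  !(nrow(rs) && any(.overlaps(rs$start, rs$start + rs$width, lo, hi)))
}

#' Generate one inter-MBS spacer
#'
#' Draws random RNA of length `spacer_len` and rejects candidates that,
#' in the context `left_context + spacer + right_context`, create a new
#' seed match (>= 6mer) to the target miRNA or a forbidden restriction
#' recognition sequence overlapping the spacer. Deterministic for a
#' fixed seed.
#'
#' @param p [design_params()].
#' @param left_context,right_context flanking sequences (`nt_seq`,
#'   [build_mbs()] result, or character) used for the constraint check.
#' @param target the target [mirna()] the sponge must not gain extra
#'   sites for.
#' @param rng_seed seed for this search (defaults to `p$rng_seed`).
#' @param max_attempts rejection-sampling budget.
#' @return Linear RNA `nt_seq` of length `spacer_len`.
#' @export
make_spacer <- function(p, left_context, right_context, target,
                        rng_seed = p$rng_seed, max_attempts = 200L) {
  stopifnot(inherits(p, "design_params"), inherits(target, "mirna"))
  if (p$spacer_len == 0L) return(rna(""))
  as_str <- function(x) {
    if (inherits(x, "mbs")) x <- x$seq
    as.character(as_nt_seq(x))
  }
  left <- as_str(left_context)
  right <- as_str(right_context)
  .with_seed(rng_seed, {
    for (i in seq_len(max_attempts)) {
      cand <- paste(sample(NT_RNA, p$spacer_len, replace = TRUE),
                    collapse = "")
      if (.spacer_ok(cand, left, right, target, p)) return(rna(cand))
    }
    stop("spacer constraint search failed after ", max_attempts,
         " attempts; try a different rng_seed", call. = FALSE)
  })
}

.gap_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) + 104729 * i) %% 2147483647)
}

#' Assemble the sponge insert
#'
#' Builds the full DNA insert for directional cloning:
#' `flank5 recognition + [MBS (+ spacer)] x n + flank3 recognition`,
#' with `n_mbs` tandem binding sites and `n_mbs - 1` spacers strictly
#' between consecutive MBS. The emitted strand is the transcript-sense
#' strand (T for U). The returned construct carries an ordered feature
#' table that tiles the insert exactly.
#'
#' Insert length obeys
#' `|flank5| + n_mbs * L + (n_mbs - 1) * spacer_len + |flank3|`
#' for an L-nt miRNA (190 bp for the 22-nt reference design).
#'
#' @param m target [mirna()].
#' @param p [design_params()].
#' @return An object of class `sponge_construct` with elements `insert`
#'   (DNA `nt_seq`), `features` (data.frame: name, kind, start, end;
#'   0-based half-open), `params`, `target` (miRNA id), `target_mirna`
#'   and `mbs`.
#' @examples
#' sc <- assemble_insert(mir21(), design_params())
#' length(sc$insert)
#' @export
assemble_insert <- function(m, p = design_params()) {
  .validate_design(m, p)
  mbs <- build_mbs(m, p)
  n <- p$n_mbs
  spacers <- character(0)
  if (n > 1L) {
    spacers <- vapply(seq_len(n - 1L), function(i) {
      gs <- .gap_seed(p$rng_seed, if (p$spacer_policy == "fixed") 1L else i)
      as.character(make_spacer(p, mbs, mbs, m, rng_seed = gs))
    }, "")
  }
  parts <- character(0)
  names_ <- character(0)
  kinds <- character(0)
  parts <- c(parts, p$flank5$recognition$residues)
  names_ <- c(names_, "flank5"); kinds <- c(kinds, "flank5")
  mbs_dna <- back_transcribe(mbs$seq)$residues
  for (i in seq_len(n)) {
    parts <- c(parts, mbs_dna)
    names_ <- c(names_, paste0("MBS", i)); kinds <- c(kinds, "MBS")
    if (i < n) {
      parts <- c(parts, chartr("U", "T", spacers[i]))
      names_ <- c(names_, paste0("spacer", i)); kinds <- c(kinds, "spacer")
    }
  }
  parts <- c(parts, p$flank3$recognition$residues)
  names_ <- c(names_, "flank3"); kinds <- c(kinds, "flank3")

  lens <- nchar(parts)
  ends <- cumsum(lens)
  feats <- data.frame(name = names_, kind = kinds,
                      start = as.integer(ends - lens),
                      end = as.integer(ends),
                      stringsAsFactors = FALSE)
  # zero-length spacers are a layout choice, not a feature
  feats <- feats[feats$end > feats$start, , drop = FALSE]
  rownames(feats) <- NULL
  structure(list(
    insert = dna(paste(parts, collapse = "")),
    features = feats,
    params = p,
    target = m$id,
    target_mirna = m,
    mbs = mbs
  ), class = "sponge_construct")
}

#' @export
print.sponge_construct <- function(x, ...) {
  cat(sprintf("<sponge_construct for %s: %d bp, %d MBS>\n", x$target,
              length(x$insert), sum(x$features$kind == "MBS")))
  f <- x$features
  cat(sprintf("  %-8s %-7s %5s..%-5s %s\n", f$name, f$kind,
              f$start + 1L, f$end,
              substring(x$insert$residues, f$start + 1L, f$end)), sep = "")
  invisible(x)
}

#' @export
summary.sponge_construct <- function(object, ...) {
  p <- object$params
  cat(sprintf("Sponge insert for %s\n", object$target))
  cat(sprintf("  length: %d bp; %d MBS of %d nt; %d spacers of %d nt\n",
              length(object$insert), p$n_mbs, length(object$mbs$seq),
              max(0L, p$n_mbs - 1L), p$spacer_len))
  bw <- if (is.null(p$bulge_window)) "none"
        else paste(p$bulge_window, collapse = "-")
  cat(sprintf("  bulge (miRNA positions): %s; flanks %s/%s; seed %d\n",
              bw, p$flank5$name, p$flank3$name, p$rng_seed))
  invisible(object)
}

#' Validate a sponge construct
#'
#' Runs the full in-silico QC panel against a construct:
#' \describe{
#'   \item{site_count}{the transcribed insert contains exactly `n_mbs`
#'     full target sites (scanner-verified).}
#'   \item{mbs_duplex}{every MBS pairs the target perfectly over the
#'     seed and carries exactly the bulge-width mismatches, all inside
#'     the bulge window.}
#'   \item{restriction}{no forbidden recognition sequence occurs inside
#'     the insert; the two terminal flank copies are exempt.}
#'   \item{decoy_offtargets}{no decoy miRNA has a strong (7mer or 8mer)
#'     seed match anywhere on the transcript.}
#'   \item{tiling}{the feature table tiles the insert exactly in the
#'     order flank5, (MBS, spacer)..., MBS, flank3.}
#' }
#' Failures are report rows, never exceptions.
#'
#' @param construct a [assemble_insert()] result.
#' @param m target [mirna()] (defaults to the construct's own target).
#' @param decoys list of decoy [mirna()] for the off-target check (see
#'   [generate_decoy_panel()]).
#' @return An object of class `validation_report`: data.frame `checks`
#'   (check, pass, detail) plus overall `pass`.
#' @export
validate_construct <- function(construct, m = construct$target_mirna,
                               decoys = list()) {
  stopifnot(inherits(construct, "sponge_construct"), inherits(m, "mirna"))
  p <- construct$params
  tx <- transcribe(construct$insert)
  checks <- list()
  add <- function(check, pass, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  sites <- find_full_sites(tx, m, bulge_window = p$bulge_window)
  add("site_count", nrow(sites) == p$n_mbs,
      sprintf("%d full sites found, %d expected", nrow(sites), p$n_mbs))

  width <- .bulge_width(p)
  mbs_feats <- construct$features[construct$features$kind == "MBS", ,
                                  drop = FALSE]
  duplex_ok <- TRUE
  duplex_why <- sprintf("%d MBS with perfect seed pairing and %d bulge mismatches",
                        nrow(mbs_feats), width)
  for (i in seq_len(nrow(mbs_feats))) {
    site <- rna(substr(tx$residues, mbs_feats$start[i] + 1L,
                       mbs_feats$end[i]))
    d <- pair_duplex(m, site)
    seed_ok <- all(.chars(d$pairing)[seq(m$seed_range[1],
                                         m$seed_range[2])] == "|")
    mm_ok <- d$n_mismatch == width &&
      (width == 0L || (all(d$mismatch_positions >= p$bulge_window[1]) &&
                       all(d$mismatch_positions <= p$bulge_window[2])))
    if (!seed_ok || !mm_ok) {
      duplex_ok <- FALSE
      duplex_why <- sprintf("%s fails duplex check (%d mismatches at %s)",
                            mbs_feats$name[i], d$n_mismatch,
                            paste(d$mismatch_positions, collapse = ","))
      break
    }
  }
  add("mbs_duplex", duplex_ok, duplex_why)

  rs <- find_restriction_sites(construct$insert, p$forbidden_enzymes)
  ins_len <- length(construct$insert)
  exempt <- (rs$enzyme == p$flank5$name & rs$start == 0L) |
            (rs$enzyme == p$flank3$name &
             rs$start == ins_len - rs$width)
  internal <- rs[!exempt, , drop = FALSE]
  add("restriction", nrow(internal) == 0L,
      if (nrow(internal) == 0L) "no internal forbidden sites"
      else sprintf("internal site(s): %s",
                   paste(sprintf("%s@%d", internal$enzyme, internal$start),
                         collapse = ", ")))

  n_strong <- 0L
  offenders <- character(0)
  for (d in decoys) {
    hits <- find_seed_matches(tx, d)
    strong <- hits[hits$site_class %in% c("7mer-A1", "7mer-m8", "8mer"), ,
                   drop = FALSE]
    if (nrow(strong)) {
      n_strong <- n_strong + nrow(strong)
      offenders <- c(offenders, d$id)
    }
  }
  add("decoy_offtargets", n_strong == 0L,
      if (n_strong == 0L)
        sprintf("no strong seed match for %d decoy(s)", length(decoys))
      else sprintf("%d strong match(es) for: %s", n_strong,
                   paste(unique(offenders), collapse = ", ")))

  f <- construct$features
  expected_kinds <- c("flank5",
                      if (p$spacer_len > 0L)
                        utils::head(rep(c("MBS", "spacer"), p$n_mbs), -1L)
                      else rep("MBS", p$n_mbs),
                      "flank3")
  tiling_ok <- nrow(f) == length(expected_kinds) &&
    identical(f$kind, expected_kinds) &&
    f$start[1] == 0L && f$end[nrow(f)] == ins_len &&
    (nrow(f) == 1L || all(f$start[-1] == f$end[-nrow(f)]))
  add("tiling", tiling_ok,
      if (tiling_ok) "features tile the insert exactly"
      else "feature table does not tile the insert")

  checks <- do.call(rbind, checks)
  rownames(checks) <- NULL
  structure(list(checks = checks, pass = all(checks$pass),
                 target = m$id, n_decoys = length(decoys)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report for %s: %s>\n", x$target,
              if (x$pass) "PASS" else "FAIL"))
  status <- ifelse(x$checks$pass, "ok  ", "FAIL")
  cat(sprintf("  [%s] %-16s %s\n", status, x$checks$check,
              x$checks$detail), sep = "")
  invisible(x)
}

#' Serialize a validation report
#'
#' @param report a [validate_construct()] result.
#' @param path optional output file; when given the text is written
#'   there and returned invisibly.
#' @return `validation_tsv`: tab-separated text (check, pass, detail);
#'   `validation_json`: a JSON string.
#' @export
validation_tsv <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(report$checks, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname validation_tsv
#' @export
validation_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  x <- list(target = report$target, pass = report$pass,
            n_decoys = report$n_decoys, checks = report$checks)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
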