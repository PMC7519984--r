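#' Duplex scoring scheme for plant miRNA target sites
#'
#' The expectation score of a miRNA-target duplex is the sum of
#' per-position penalties: 0 for a Watson-Crick match, 0.5 for a G:U
#' wobble, 1 for a mismatch and 2 for each gapped position, with every
#' penalty doubled inside the seed region (miRNA positions 2-13 by
#' default, counted from the miRNA 5' end). Lower is better; a perfect
#' complement scores 0. Disruption (mismatch or gap) of the central
#' positions 10-11 switches the predicted regulation mode from cleavage
#' to translation inhibition, reflecting that plant miRNA-guided
#' cleavage happens between target bases opposite miRNA positions 10
#' and 11.
#'
#' @param match,wobble,mismatch,gap Per-position penalties.
#' @param seed_from,seed_to Seed region bounds (inclusive, miRNA
#'   coordinates) over which penalties are doubled.
#' @param central miRNA positions whose disruption implies translation
#'   inhibition.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 0, wobble = 0.5, mismatch = 1, gap = 2,
                           seed_from = 2, seed_to = 13,
                           central = c(10L, 11L)) {
  stopifnot(match >= 0, wobble >= 0, mismatch >= 0, gap >= 0,
            seed_from >= 1, seed_to >= seed_from)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap = gap, seed_from = seed_from, seed_to = seed_to,
                 central = as.integer(central)),
            class = "scoring_scheme")
}

# base encoding A C G U N -> 0..4
encode_rna <- function(seq) {
  v <- utf8ToInt(chartr("tT", "uU", toupper(seq)))
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 0L
  code[v == utf8ToInt("C")] <- 1L
  code[v == utf8ToInt("G")] <- 2L
  code[v == utf8ToInt("U")] <- 3L
  code[v == utf8ToInt("N")] <- 4L
  if (any(!v %in% utf8ToInt("ACGUN") & TRUE)) {
    ok <- intToUtf8(v, multiple = TRUE) %in% c("A", "C", "G", "U", "N")
    if (!all(ok)) mh_abort("illegal RNA character", "format_error")
  }
  code
}

# 5x5 row-major per-pair penalty lookup (mir base x site base)
pair_penalty_lookup <- function(scheme) {
  pen <- matrix(scheme$mismatch, 5, 5)
  wc <- rbind(c(1, 4), c(4, 1), c(3, 2), c(2, 3))   # A:U U:A G:C C:G
  for (k in seq_len(nrow(wc))) pen[wc[k, 1], wc[k, 2]] <- scheme$match
  pen[3, 4] <- scheme$wobble  # G:U
  pen[4, 3] <- scheme$wobble  # U:G
  pen[5, ] <- scheme$mismatch # N pairs nothing
  pen[, 5] <- scheme$mismatch
  as.vector(t(pen))
}

position_weights <- function(L, scheme) {
  ifelse(seq_len(L) >= scheme$seed_from & seq_len(L) <= scheme$seed_to, 2, 1)
}

pair_code <- function(mb, sb, scheme) {
  wc <- (mb == "A" & sb == "U") | (mb == "U" & sb == "A") |
    (mb == "G" & sb == "C") | (mb == "C" & sb == "G")
  gu <- (mb == "G" & sb == "U") | (mb == "U" & sb == "G")
  ifelse(wc, "M", ifelse(gu, "W", "X"))
}

# Build the alignment column string for a site found by the scanner.
# Codes, ordered along the miRNA 5'->3': M match, W wobble, X mismatch,
# g unpaired miRNA base, b bulged transcript base. The site sequence is
# given 5'->3' and consumed from its 3' end.
duplex_columns <- function(mirna, site, gap_type, gap_pos) {
  mb <- strsplit(mirna, "")[[1]]
  sb <- rev(strsplit(site, "")[[1]])  # site 3'->5', aligned with miRNA 5'->3'
  L <- length(mb)
  if (gap_type == 0) {
    codes <- pair_code(mb, sb, NULL)
    mpos <- seq_len(L)
  } else if (gap_type == 1) {      # miRNA base gap_pos unpaired
    j <- gap_pos
    paired <- pair_code(mb[-j], sb, NULL)
    codes <- append(paired, "g", after = j - 1)
    mpos <- seq_len(L)
  } else {                         # bulged site base between j and j+1
    j <- gap_pos
    bulge_site_idx <- j + 1        # index into sb (3'->5'): after j pairs
    paired <- pair_code(mb, sb[-bulge_site_idx], NULL)
    codes <- append(paired, "b", after = j)
    mpos <- append(seq_len(L), j + 1, after = j)
  }
  list(codes = codes, mpos = mpos)
}

score_columns <- function(codes, mpos, scheme) {
  base <- c(M = scheme$match, W = scheme$wobble, X = scheme$mismatch,
            g = scheme$gap, b = scheme$gap)[codes]
  wt <- ifelse(mpos >= scheme$seed_from & mpos <= scheme$seed_to, 2, 1)
  sum(base * wt)
}

#' Score a miRNA-target duplex alignment
#'
#' Computes the expectation penalty of one duplex under a
#' [scoring_scheme()]. The alignment is a string of per-column codes
#' ordered along the miRNA 5'->3' (`M` match, `W` G:U wobble, `X`
#' mismatch, `g` unpaired miRNA base, `b` bulged site base); the site
#' sequence is given 5'->3' and pairs antiparallel. With `alignment =
#' NULL` the two sequences must have equal length and are paired
#' gaplessly, the codes being derived from the bases. A supplied
#' alignment is validated against the sequences: its `M`/`W`/`X` columns
#' must agree with the base pairing they claim.
#'
#' @param mirna miRNA sequence, 5'->3' RNA.
#' @param site Target site sequence, 5'->3' RNA.
#' @param alignment Optional column-code string; `NULL` for gapless.
#' @param scheme A [scoring_scheme()].
#' @return The expectation penalty (a single non-negative number).
#' @export
#' @examples
#' score_duplex("ACGUACGUACGUACGUACGUA", rna_revcomp("ACGUACGUACGUACGUACGUA"))
score_duplex <- function(mirna, site, alignment = NULL,
                         scheme = scoring_scheme()) {
  mirna <- chartr("tT", "uU", toupper(mirna))
  site <- chartr("tT", "uU", toupper(site))
  mb <- strsplit(mirna, "")[[1]]
  sb_rev <- rev(strsplit(site, "")[[1]])
  L <- length(mb)
  if (is.null(alignment)) {
    if (nchar(site) != L) {
      mh_abort("gapless scoring needs sequences of equal length",
               "alignment_error")
    }
    cols <- duplex_columns(mirna, site, 0, 0)
    return(score_columns(cols$codes, cols$mpos, scheme))
  }
  codes <- strsplit(alignment, "")[[1]]
  if (!all(codes %in% c("M", "W", "X", "g", "b"))) {
    mh_abort("alignment codes must be M, W, X, g or b", "alignment_error")
  }
  if (sum(codes != "b") != L || sum(codes != "g") != nchar(site)) {
    mh_abort("alignment length inconsistent with the sequences",
             "alignment_error")
  }
  mi <- 0L; si <- 0L
  mpos <- integer(length(codes))
  for (k in seq_along(codes)) {
    if (codes[k] %in% c("M", "W", "X")) {
      mi <- mi + 1L; si <- si + 1L
      mpos[k] <- mi
      want <- pair_code(mb[mi], sb_rev[si], scheme)
      if (want != codes[k]) {
        mh_abort(sprintf(
          "alignment column %d claims %s but bases %s:%s form %s",
          k, codes[k], mb[mi], sb_rev[si], want), "alignment_error")
      }
    } else if (codes[k] == "g") {
      mi <- mi + 1L
      mpos[k] <- mi
    } else {
      si <- si + 1L
      mpos[k] <- min(mi + 1L, L)
    }
  }
  score_columns(codes, mpos, scheme)
}

#' Classify the regulation mode of a target site
#'
#' `translation_inhibition` when a mismatch or gap occupies a central
#' miRNA position (10 or 11 under the default scheme), `cleavage`
#' otherwise. G:U wobbles do not disrupt cleavage.
#'
#' @param alignment Column-code string as produced by
#'   [scan_transcript()] (codes `M`, `W`, `X`, `g`, `b`).
#' @param scheme A [scoring_scheme()].
#' @return `"cleavage"` or `"translation_inhibition"`.
#' @export
classify_mode <- function(alignment, scheme = scoring_scheme()) {
  codes <- strsplit(alignment, "")[[1]]
  mi <- 0L
  L <- sum(codes != "b")
  for (k in seq_along(codes)) {
    if (codes[k] %in% c("M", "W", "X", "g")) {
      mi <- mi + 1L
      pos <- mi
    } else {
      pos <- min(mi + 1L, L)
    }
    if (codes[k] %in% c("X", "g", "b") && pos %in% scheme$central) {
      return("translation_inhibition")
    }
  }
  "cleavage"
}

#' Scan a transcript for target sites of one miRNA
#'
#' Evaluates the duplex of the miRNA against every transcript window,
#' enumerating the gapless register and (with `max_gaps = 1`) every
#' single-bulge variant on either strand, and keeps alignments whose
#' expectation is at most `cutoff`. Overlapping sites are collapsed to
#' the best-scoring one (ties broken by smallest start). Coordinates are
#' 1-based, fully closed, on the transcript 5'->3'.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param transcript Transcript sequence (RNA/DNA accepted).
#' @param cutoff Maximum expectation to report (default 3).
#' @param max_gaps Maximum bulged positions per duplex (0 or 1).
#' @param scheme A [scoring_scheme()].
#' @return Tibble with `start`, `end`, `expectation`, `alignment`,
#'   `mode`, sorted by (expectation, start).
#' @export
scan_transcript <- function(mirna, transcript, cutoff = 3, max_gaps = 1,
                            scheme = scoring_scheme()) {
  mirna <- chartr("tT", "uU", toupper(mirna))
  transcript <- chartr("tT", "uU", toupper(transcript))
  if (nchar(mirna) == 0 || nchar(transcript) == 0) {
    mh_abort("empty sequence", "format_error")
  }
  if (nchar(transcript) < nchar(mirna)) {
    mh_abort("transcript shorter than the miRNA", "format_error")
  }
  stopifnot(max_gaps %in% c(0, 1))
  L <- nchar(mirna)
  hits <- scan_windows_cpp(encode_rna(mirna), encode_rna(transcript),
                           pair_penalty_lookup(scheme),
                           position_weights(L, scheme),
                           scheme$gap, cutoff, as.integer(max_gaps))
  if (nrow(hits) == 0) {
    return(tibble(start = integer(), end = integer(),
                  expectation = double(), alignment = character(),
                  mode = character()))
  }
  wlen <- L + c(`0` = 0L, `1` = -1L, `2` = 1L)[as.character(hits[, "gap_type"])]
  out <- tibble(
    start = as.integer(hits[, "start"]),
    end = as.integer(hits[, "start"]) + as.integer(wlen) - 1L,
    expectation = unname(hits[, "expectation"]),
    gap_type = as.integer(hits[, "gap_type"]),
    gap_pos = as.integer(hits[, "gap_pos"])
  )
  out <- arrange(out, .data$expectation, .data$start, .data$gap_type)
  # collapse overlapping sites, best first
  keep <- logical(nrow(out))
  taken_s <- integer(0); taken_e <- integer(0)
  for (k in seq_len(nrow(out))) {
    if (!any(out$start[k] <= taken_e & out$end[k] >= taken_s)) {
      keep[k] <- TRUE
      taken_s <- c(taken_s, out$start[k])
      taken_e <- c(taken_e, out$end[k])
    }
  }
  out <- out[keep, ]
  aln <- purrr::pmap_chr(out, function(start, end, expectation, gap_type,
                                       gap_pos) {
    site <- substr(transcript, start, end)
    paste(duplex_columns(mirna, site, gap_type, gap_pos)$codes,
          collapse = "")
  })
  out |>
    mutate(alignment = aln,
           mode = purrr::map_chr(aln, classify_mode, scheme = scheme)) |>
    select("start", "end", "expectation", "alignment", "mode")
}

#' Predict targets for sets of miRNAs and transcripts
#'
#' Scans every (miRNA, transcript) pair with [scan_transcript()] and
#' keeps, per pair, the best passing site. When a family map is given,
#' predictions of family members are merged: each (family, transcript)
#' appears once, carried by the best-scoring member site, which removes
#' the repeated genes that near-identical family members otherwise
#' predict independently.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @inheritParams scan_transcript
#' @param families Optional tibble `mirna_id`, `family`; default derives
#'   families with [map_to_family()] (lenient: unparsable ids form their
#'   own family).
#' @return Tibble `mirna_id`, `family`, `transcript_id`, `start`, `end`,
#'   `expectation`, `mode`, `alignment`.
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 3, max_gaps = 1,
                            scheme = scoring_scheme(), families = NULL) {
  if (length(mirnas) == 0 || length(transcripts) == 0) {
    mh_abort("non-empty miRNA and transcript sets required", "format_error")
  }
  if (is.null(families)) {
    families <- tibble(mirna_id = names(mirnas)) |>
      mutate(family = suppressWarnings(
        map_to_family(.data$mirna_id, lenient = TRUE)))
  }
  rows <- purrr::map(names(mirnas), function(mid) {
    purrr::map(names(transcripts), function(tid) {
      sites <- scan_transcript(mirnas[[mid]], transcripts[[tid]],
                               cutoff = cutoff, max_gaps = max_gaps,
                               scheme = scheme)
      if (nrow(sites) == 0) return(NULL)
      best <- sites[1, ]  # already sorted by (expectation, start)
      mutate(best, mirna_id = mid, transcript_id = tid)
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(rows) == 0) {
    return(tibble(mirna_id = character(), family = character(),
                  transcript_id = character(), start = integer(),
                  end = integer(), expectation = double(),
                  mode = character(), alignment = character()))
  }
  rows <- left_join(rows, families, by = "mirna_id")
  rows |>
    group_by(.data$family, .data$transcript_id) |>
    arrange(.data$expectation, .data$start, .data$mirna_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$family, .data$transcript_id) |>
    select("mirna_id", "family", "transcript_id", "start", "end",
           "expectation", "mode", "alignment")
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA (or DNA) sequence string.
#' @return The reverse complement in the RNA alphabet.
#' @export
#' @examples
#' rna_revcomp("ACGU")
rna_revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- chartr("tT", "uU", toupper(s))
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
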