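# Independent brute-force duplex scanner used as the oracle for the
# compiled scanner: plain character-level loops, no shared code with
# the implementation.

bf_penalty <- function(mb, sb, scheme = scoring_scheme()) {
  key <- paste0(mb, sb)
  if (key %in% c("AU", "UA", "GC", "CG")) return(scheme$match)
  if (key %in% c("GU", "UG")) return(scheme$wobble)
  scheme$mismatch
}

bf_weight <- function(pos, scheme = scoring_scheme()) {
  if (pos >= scheme$seed_from && pos <= scheme$seed_to) 2 else 1
}

# Enumerate every window and single-bulge placement; returns the raw
# hit table (start, gap_type, gap_pos, expectation) with expectation
# <= cutoff, like the compiled scanner before overlap collapsing.
bf_scan <- function(mirna, transcript, cutoff = 3, max_gaps = 1,
                    scheme = scoring_scheme()) {
  mb <- strsplit(mirna, "")[[1]]
  tb <- strsplit(transcript, "")[[1]]
  L <- length(mb); N <- length(tb)
  rows <- list()
  add <- function(s, gt, gp, e) {
    if (e <= cutoff) {
      rows[[length(rows) + 1]] <<- data.frame(
        start = s, gap_type = gt, gap_pos = gp, expectation = e)
    }
  }
  # gapless: miRNA pos i pairs window base (L - i + 1)
  for (s in seq_len(N - L + 1)) {
    w <- tb[s:(s + L - 1)]
    e <- 0
    for (i in seq_len(L)) {
      e <- e + bf_penalty(mb[i], w[L - i + 1], scheme) * bf_weight(i, scheme)
    }
    add(s, 0, 0, e)
  }
  if (max_gaps >= 1 && L >= 2) {
    # miRNA base j unpaired, window length L - 1
    for (j in seq_len(L)) {
      for (s in seq_len(N - (L - 1) + 1)) {
        w <- tb[s:(s + L - 2)]
        e <- scheme$gap * bf_weight(j, scheme)
        for (i in seq_len(L)) {
          if (i == j) next
          widx <- if (i < j) L - i else L - i + 1
          e <- e + bf_penalty(mb[i], w[widx], scheme) * bf_weight(i, scheme)
        }
        add(s, 1, j, e)
      }
    }
    # bulged transcript base between miRNA positions j and j+1,
    # window length L + 1, gap charged at position j + 1
    for (j in seq_len(L - 1)) {
      for (s in seq_len(N - (L + 1) + 1)) {
        w <- tb[s:(s + L)]
        e <- scheme$gap * bf_weight(j + 1, scheme)
        for (i in seq_len(L)) {
          widx <- if (i <= j) L + 2 - i else L + 1 - i
          e <- e + bf_penalty(mb[i], w[widx], scheme) * bf_weight(i, scheme)
        }
        add(s, 2, j, e)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), gap_type = integer(),
                      gap_pos = integer(), expectation = double()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$gap_type, out$gap_pos), ]
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

# small expression matrix with a hand-set layout: 5 timepoints x 2 reps
toy_sheet <- function(timepoints = heat_timepoints(), reps = 2) {
  data.frame(
    sample_id = paste0(rep(timepoints, each = reps), "_r",
                       rep(seq_len(reps), length(timepoints))),
    timepoint = rep(timepoints, each = reps),
    replicate = rep(seq_len(reps), length(timepoints)))
}

toy_matrix <- function(values, flags = NULL, timepoints = heat_timepoints(),
                       reps = 2) {
  sheet <- toy_sheet(timepoints, reps)
  colnames(values) <- sheet$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("p", seq_len(nrow(values)))
  }
  if (!is.null(flags)) dimnames(flags) <- dimnames(values)
  expr_matrix(values, sheet, flags = flags, timepoint_levels = timepoints)
}

# long-format DE profile table from a compact spec:
# list(entity = list("10min" = c(lfc, p), ...))
toy_profiles <- function(spec, timepoints = c("10min", "20min", "60min", "2h")) {
  rows <- list()
  for (ent in names(spec)) {
    for (tp in timepoints) {
      v <- spec[[ent]][[tp]]
      if (is.null(v)) v <- c(0, 1)
      rows[[length(rows) + 1]] <- data.frame(
        entity_id = ent, timepoint = tp, log2fc = v[1], pvalue = v[2])
    }
  }
  df <- do.call(rbind, rows)
  df$timepoint <- factor(df$timepoint, levels = timepoints, ordered = TRUE)
  tibble::as_tibble(df)
}
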