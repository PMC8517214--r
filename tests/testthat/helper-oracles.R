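# Independent oracles and small fixture builders shared across tests.

BASES <- c("A", "C", "G", "T")

# brute-force transitive-closure interval merge (O(n^2)); the oracle for
# merge_intervals
brute_merge <- function(x, gap) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  parts <- split(x, x$chrom)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]][, c("start", "end")]
    groups <- as.list(seq_len(nrow(p)))
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        if (merged) break
        for (j in seq_along(groups)) {
          if (i >= j) next
          si <- min(p$start[groups[[i]]]); ei <- max(p$end[groups[[i]]])
          sj <- min(p$start[groups[[j]]]); ej <- max(p$end[groups[[j]]])
          if (sj <= ei + gap && si <= ej + gap) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    do.call(rbind, lapply(groups, function(g)
      data.frame(chrom = ch,
                 start = min(p$start[g]), end = max(p$end[g]))))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2")) {
  start <- sample.int(10000L, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(300L, n, replace = TRUE),
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             name = sprintf("iv%03d", seq_len(n)),
             score = round(stats::runif(n), 3))
}

random_pwm <- function(width, id = paste0("rnd", width)) {
  m <- matrix(stats::rgamma(4L * width, 0.8), 4L)
  m <- sweep(m, 2L, colSums(m), "/")
  pwm(id, m)
}

# near-point-mass PWM on a word (concentration < 1 keeps log-odds finite)
word_pwm <- function(id, word, conc = 0.95) {
  w <- nchar(word)
  m <- matrix((1 - conc) / 3, 4L, w)
  m[cbind(match(strsplit(word, "")[[1L]], BASES), seq_len(w))] <- conc
  pwm(id, m)
}

# exact point-mass PWM (tiny off-probabilities, zero pseudocount)
point_pwm <- function(id, word) {
  w <- nchar(word)
  m <- matrix(1e-12, 4L, w)
  m[cbind(match(strsplit(word, "")[[1L]], BASES), seq_len(w))] <- 1
  m <- sweep(m, 2L, colSums(m), "/")
  pwm(id, m, pseudocount = 0)
}

# brute-force both-strand window scoring; the oracle for scan_sequence
brute_scan <- function(p, s, thr) {
  w <- p$width
  L <- nchar(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  if (L >= w) {
    for (i in seq_len(L - w + 1L)) {
      win <- strsplit(substr(s, i, i + w - 1L), "")[[1L]]
      if (any(!win %in% BASES)) next
      sc_f <- sum(p$lod[cbind(match(win, BASES), seq_len(w))])
      rcw <- rev(unname(comp[win]))
      sc_r <- sum(p$lod[cbind(match(rcw, BASES), seq_len(w))])
      if (sc_f >= thr - 1e-12) {
        rows[[length(rows) + 1L]] <-
          data.frame(position = i - 1L, strand = "+", score = sc_f)
      }
      if (sc_r >= thr - 1e-12) {
        rows[[length(rows) + 1L]] <-
          data.frame(position = i - 1L, strand = "-", score = sc_r)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), strand = character(),
               score = numeric())
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive word enumeration of the PWM score distribution (width <= 8);
# the oracle for score_threshold / score_tail_prob. Scores and
# probabilities stay aligned because both expand in the same base order.
enumerate_words <- function(p) {
  score <- 0
  prob <- 1
  for (j in seq_len(p$width)) {
    score <- as.vector(outer(score, p$lod[, j], "+"))
    prob <- as.vector(outer(prob, p$background, "*"))
  }
  list(score = score, prob = prob / sum(prob))
}

# threshold oracle: validity (the set admitted by thr has null mass <=
# pc) and minimality (any attainable score clearly below thr would exceed
# pc), both up to the documented per-position discretization of 1e-3 bits
check_threshold_oracle <- function(p, pc) {
  en <- enumerate_words(p)
  tol <- p$width * 1e-3 + 1e-9
  thr <- score_threshold(p, pc)
  testthat::expect_lte(sum(en$prob[en$score >= thr + tol]), pc)
  below <- en$score[en$score < thr - tol]
  if (length(below)) {
    testthat::expect_gt(sum(en$prob[en$score >= max(below) - 1e-12]), pc)
  }
  invisible(thr)
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c(BASES, "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4L), p_n)), collapse = "")
}

# small NB count matrix with two groups
nb_fixture <- function(n, muA, muB, disp, reps = 3L) {
  m <- cbind(
    matrix(stats::rnbinom(n * reps, size = 1 / disp, mu = muA), n),
    matrix(stats::rnbinom(n * reps, size = 1 / disp, mu = rep(muB, reps)),
           n)
  )
  colnames(m) <- c(paste0("A", seq_len(reps)), paste0("B", seq_len(reps)))
  count_matrix(m, data.frame(sample = colnames(m)))
}

ARCH_LABEL <- c(early_peak = "early_peak", early_plateau = "early_plateau",
                late = "late", null = "unclassified")

# differential tables + clusters for a simulated gene count matrix
cluster_simulated <- function(cm) {
  grp <- function(cond) cm$samples$sample[cm$samples$condition == cond]
  classify_transcript_clusters(
    nb_differential(cm, grp("vehicle"), grp("t30")),
    nb_differential(cm, grp("vehicle"), grp("t120")),
    nb_differential(cm, grp("t30"), grp("t120"))
  )
}

table1_path <- function() {
  system.file("extdata", "ahr_early_peak_targets.tsv",
              package = "tfdynamics")
}
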