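#' Band a confidence rating
#'
#' Ratings of 7 or above are `high`, 5-6 `medium`, 4 or below `low`.
#'
#' @param rating Integer vector of ratings in 1..9 (NA allowed, banded as
#'   `none`).
#' @return Factor with levels high, medium, low, none.
#' @export
band_confidence <- function(rating) {
  ok <- is.na(rating) | (rating >= 1 & rating <= 9 & rating == round(rating))
  if (!all(ok)) stop("confidence rating out of range 1..9")
  out <- ifelse(is.na(rating), "none",
                ifelse(rating >= 7, "high", ifelse(rating >= 5, "medium", "low")))
  factor(out, levels = c("high", "medium", "low", "none"))
}

#' Cluster reaction times into fast / medium / slow classes
#'
#' 1-D k-means with k = 4 on the non-missing RTs: one deterministic start at
#' the 12.5/37.5/62.5/87.5 percentiles plus 9 seeded random restarts, best
#' within-cluster sum of squares wins; centres sorted ascending. Trials below
#' the second centre are `fast`, between the second and third centre
#' (inclusive at both boundaries) `medium`, above the third centre `slow`;
#' missing RTs are `none`.
#'
#' @param rts Numeric vector of reaction times (s); NAs allowed.
#' @param seed Seed for the random restarts.
#' @return List: `labels` (factor fast/medium/slow/none, same length as
#'   `rts`), `centres` (sorted, length 4), `assignment` (cluster index per
#'   non-missing RT).
#' @export
cluster_rts <- function(rts, seed = 1) {
  x <- rts[!is.na(rts)]
  if (length(x) < 8) stop("need at least 8 non-missing RTs")
  if (length(unique(x)) < 4) stop("need at least 4 distinct RT values")
  starts <- list(matrix(stats::quantile(x, c(0.125, 0.375, 0.625, 0.875),
                                        names = FALSE)))
  rng <- local_rng(seed)
  for (i in 1:9) starts[[i + 1]] <- matrix(sample(unique(x), 4))
  rng()
  best <- NULL
  for (st in starts) {
    km <- tryCatch(suppressWarnings(stats::kmeans(x, centers = st)),
                   error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed on the supplied RTs")
  centres <- sort(as.numeric(best$centers))
  lab <- rep("none", length(rts))
  present <- !is.na(rts)
  eps <- 1e-9 * max(1, max(abs(x)))  # boundary RTs belong to "medium"
  lab[present] <- ifelse(rts[present] < centres[2] - eps, "fast",
                         ifelse(rts[present] > centres[3] + eps, "slow",
                                "medium"))
  list(labels = factor(lab, levels = c("fast", "medium", "slow", "none")),
       centres = centres,
       assignment = best$cluster)
}

#' Screen participants by confidence-RT rank correlation
#'
#' Spearman rank correlation between confidence rating and RT per
#' participant (two-sided); a participant is included iff p < alpha.
#' Participants with constant confidence or constant RT are excluded with
#' reason "degenerate".
#'
#' @param tables A behavior data.frame (columns `participant`, `rt`,
#'   `confidence`) or a list of per-participant data.frames.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with columns `participant`, `n`, `rho`, `p`,
#'   `included`, `reason`.
#' @export
screen_participants <- function(tables, alpha = 0.05) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  out <- lapply(split(tab, tab$participant), function(d) {
    d <- d[!is.na(d$rt) & !is.na(d$confidence), ]
    if (nrow(d) < 10)
      return(data.frame(participant = d$participant[1], n = nrow(d),
                        rho = NA_real_, p = NA_real_, included = FALSE,
                        reason = "too few trials"))
    if (length(unique(d$confidence)) < 2 || length(unique(d$rt)) < 2)
      return(data.frame(participant = d$participant[1], n = nrow(d),
                        rho = NA_real_, p = NA_real_, included = FALSE,
                        reason = "degenerate"))
    ct <- suppressWarnings(stats::cor.test(d$confidence, d$rt,
                                           method = "spearman", exact = FALSE))
    data.frame(participant = d$participant[1], n = nrow(d),
               rho = unname(ct$estimate), p = ct$p.value,
               included = ct$p.value < alpha, reason = "")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fast-versus-slow accuracy contrast across participants
#'
#' Computes each participant's mean accuracy over fast-labeled and
#' slow-labeled trials and compares them with the paired Wilcoxon
#' signed-rank test across participants. Reports both the one-sided
#' (fast > slow) and two-sided p-values.
#'
#' @param tables Behavior data.frame with columns `participant`, `rt`,
#'   `correct`; missing-RT trials are ignored.
#' @param labels Optional factor of fast/medium/slow labels aligned with the
#'   rows of `tables`; if NULL, [cluster_rts()] is applied per participant.
#' @param seed Seed forwarded to [cluster_rts()].
#' @return List: `per_participant` (data.frame participant, fast_accuracy,
#'   slow_accuracy), `statistic`, `p_one_sided`, `p_two_sided`.
#' @export
accuracy_contrast <- function(tables, labels = NULL, seed = 1) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  if (is.null(labels)) {
    labels <- rep(NA_character_, nrow(tab))
    for (pid in unique(tab$participant)) {
      idx <- tab$participant == pid
      labels[idx] <- as.character(cluster_rts(tab$rt[idx], seed = seed)$labels)
    }
  }
  labels <- as.character(labels)
  per <- lapply(split(seq_len(nrow(tab)), tab$participant), function(idx) {
    f <- idx[labels[idx] == "fast"]; s <- idx[labels[idx] == "slow"]
    if (!length(f) || !length(s))
      stop("participant ", tab$participant[idx[1]],
           " lacks fast or slow trials")
    data.frame(participant = tab$participant[idx[1]],
               fast_accuracy = mean(tab$correct[f], na.rm = TRUE),
               slow_accuracy = mean(tab$correct[s], na.rm = TRUE))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  d <- per$fast_accuracy - per$slow_accuracy
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(per_participant = per, statistic = 0, p_one_sided = 1,
                p_two_sided = 1))
  }
  w1 <- suppressWarnings(stats::wilcox.test(per$fast_accuracy,
                                            per$slow_accuracy, paired = TRUE,
                                            alternative = "greater"))
  w2 <- suppressWarnings(stats::wilcox.test(per$fast_accuracy,
                                            per$slow_accuracy, paired = TRUE))
  list(per_participant = per, statistic = unname(w1$statistic),
       p_one_sided = w1$p.value, p_two_sided = w2$p.value)
}

#' Pooled trial-level correlation between delay period and confidence
#'
#' @param tables Behavior data.frame with columns `delay` and `confidence`
#'   (pooled across participants).
#' @return List with Spearman `rho` and `p`.
#' @export
delay_confidence_check <- function(tables) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  d <- tab[!is.na(tab$delay) & !is.na(tab$confidence), ]
  ct <- suppressWarnings(stats::cor.test(d$delay, d$confidence,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Attach confidence-band and RT-class labels to a behavior table
#'
#' @param table Behavior data.frame with `rt` and `confidence` columns;
#'   labeling is per participant if a `participant` column is present.
#' @param seed Seed forwarded to [cluster_rts()].
#' @return The table with `confidence_band` and `rt_class` columns appended.
#' @export
label_behavior <- function(table, seed = 1) {
  table$confidence_band <- band_confidence(table$confidence)
  lab <- rep("none", nrow(table))
  groups <- if ("participant" %in% names(table))
    split(seq_len(nrow(table)), table$participant) else list(seq_len(nrow(table)))
  for (idx in groups)
    lab[idx] <- as.character(cluster_rts(table$rt[idx], seed = seed)$labels)
  table$rt_class <- factor(lab, levels = c("fast", "medium", "slow", "none"))
  table
}
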