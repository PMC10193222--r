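LIKERT_LEVELS <- c("strongly agree", "agree", "neutral", "disagree",
                   "strongly disagree")
LIKERT_SCORES <- c(2L, 1L, 0L, -1L, -2L)

#' Map a Likert label to its integer score
#'
#' Strongly agree, agree, neutral, disagree and strongly disagree map to
#' 2, 1, 0, -1 and -2 respectively.
#'
#' @param label character vector of rating labels.
#' @return Integer scores.
#' @examples
#' map_likert(c("strongly agree", "neutral", "strongly disagree"))
#' @export
map_likert <- function(label) {
  ix <- match(tolower(trimws(label)), LIKERT_LEVELS)
  if (anyNA(ix)) {
    stop("unknown rating label: ",
         paste(unique(label[is.na(ix)]), collapse = ", "), call. = FALSE)
  }
  LIKERT_SCORES[ix]
}

#' Mean and SD of mapped feedback scores
#'
#' @param scores integer score vector.
#' @param population use the population (n) rather than the sample (n-1) SD
#'   denominator.
#' @return list with `mean` and `sd`.
#' @export
summarize_scores <- function(scores, population = FALSE) {
  if (length(scores) == 0L) stop("no scores to summarize", call. = FALSE)
  m <- mean(scores)
  s <- if (length(scores) == 1L) 0 else stats::sd(scores)
  if (population) s <- s * sqrt((length(scores) - 1) / length(scores))
  list(mean = m, sd = s)
}

#' Wilcoxon signed-rank test of scores against zero
#'
#' Zeros are discarded (the classic procedure; set `zero_method = "pratt"`
#' to rank them in and then drop their ranks), tied absolute values receive
#' mid-ranks, and for `n <= exact_limit` the two-sided p-value is exact: the
#' null distribution of the positive-rank sum `W+` over all `2^n` sign
#' assignments is built by convolution of the rank generating functions, and
#' `p = min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`. Above the limit a normal
#' approximation with tie correction is used.
#'
#' @param scores integer (or numeric) score vector.
#' @param exact_limit largest n for the exact enumeration.
#' @param zero_method `"wilcoxon"` (discard zeros) or `"pratt"`.
#' @return list with `statistic` (`W+`), `n` (nonzero scores used), `p`
#'   (two-sided) and `method`.
#' @examples
#' wilcoxon_signed_rank_vs_zero(rep(1, 5))$p # 0.0625
#' @export
wilcoxon_signed_rank_vs_zero <- function(scores, exact_limit = 25L,
                                         zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  x <- scores[!is.na(scores)]
  if (zero_method == "wilcoxon") {
    x <- x[x != 0]
    if (length(x) == 0L) {
      stop("all scores are zero: the test is undefined", call. = FALSE)
    }
    r <- rank(abs(x))
  } else {
    if (all(x == 0)) stop("all scores are zero: the test is undefined",
                          call. = FALSE)
    r_all <- rank(abs(x))
    r <- r_all[x != 0]
    x <- x[x != 0]
  }
  n <- length(x)
  w_plus <- sum(r[x > 0])
  if (n <= exact_limit) {
    # null distribution of 2*W+ (doubling makes mid-ranks integral)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L) # counts[k+1] = #assignments with 2W+ = k
    counts[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2) # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = w_plus, n = n, p = p, method = method)
}

#' Integer percentage, ties rounded away from zero
#'
#' @param count numerator (0..n).
#' @param n denominator (> 0).
#' @return `round(100 * count / n)` as an integer, with `.5` ties rounded
#'   away from zero (so 11 of 15 gives 73 and 7 of 15 gives 47).
#' @export
percent <- function(count, n) {
  if (n <= 0) stop("denominator must be positive", call. = FALSE)
  if (count < 0 || count > n) stop("count must lie in [0, n]", call. = FALSE)
  as.integer(floor(100 * count / n + 0.5))
}

#' Summarize a Likert feedback table per game and aspect
#'
#' @param tbl data frame with columns `user_id`, `game`, `aspect`,
#'   `rating_label` (one row per user/game/aspect).
#' @param ... passed to [wilcoxon_signed_rank_vs_zero()].
#' @return data frame with one row per (game, aspect): `n`, `mean`, `sd`,
#'   `statistic`, `p`.
#' @export
analyze_feedback <- function(tbl, ...) {
  needed <- c("user_id", "game", "aspect", "rating_label")
  if (!all(needed %in% names(tbl))) {
    stop("feedback table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl[c("user_id", "game", "aspect")])) {
    stop("one rating per (user, game, aspect) expected", call. = FALSE)
  }
  tbl$score <- map_likert(tbl$rating_label)
  groups <- unique(tbl[c("game", "aspect")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sc <- tbl$score[tbl$game == g$game & tbl$aspect == g$aspect]
    sm <- summarize_scores(sc)
    wt <- wilcoxon_signed_rank_vs_zero(sc, ...)
    data.frame(game = g$game, aspect = g$aspect, n = length(sc),
               mean = sm$mean, sd = sm$sd, statistic = wt$statistic,
               p = wt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percentage summary of a multi-select question
#'
#' @param tbl data frame with `user_id` plus one logical column per option.
#' @return data frame with `option`, `count`, `n`, `percent`.
#' @export
summarize_multiselect <- function(tbl) {
  opts <- setdiff(names(tbl), "user_id")
  n <- nrow(tbl)
  data.frame(option = opts,
             count = vapply(opts, function(o) sum(as.logical(tbl[[o]])), 1L),
             n = n,
             percent = vapply(opts, function(o) {
               percent(sum(as.logical(tbl[[o]])), n)
             }, 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
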