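#' In-game economy state
#'
#' Shared bookkeeping for points, coins, lives, double jumps and badges.
#' All counters are non-negative and the badge set only ever grows within a
#' session. Badge tiers are ordered bronze < silver < gold, and a higher tier
#' implies the lower ones.
#'
#' @param points,coins,lives,free_double_jumps non-negative integer counters.
#' @param paid_life_purchases how many extra lives have been bought so far;
#'   drives the doubling cost schedule of [purchase_life()].
#' @param badges character vector, subset of `c("bronze", "silver", "gold")`.
#' @return A list of class `economy_state`.
#' @export
economy_state <- function(points = 0L, coins = 0L, lives = 0L,
                          free_double_jumps = 0L, paid_life_purchases = 0L,
                          badges = character()) {
  eco <- list(points = as.integer(points), coins = as.integer(coins),
              lives = as.integer(lives),
              free_double_jumps = as.integer(free_double_jumps),
              paid_life_purchases = as.integer(paid_life_purchases),
              badges = sort(unique(as.character(badges))))
  validate_economy(eco)
  structure(eco, class = "economy_state")
}

BADGE_TIERS <- c("bronze", "silver", "gold")

validate_economy <- function(eco) {
  cnt <- c(eco$points, eco$coins, eco$lives, eco$free_double_jumps,
           eco$paid_life_purchases)
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("economy counters must be non-negative", call. = FALSE)
  }
  if (!all(eco$badges %in% BADGE_TIERS)) {
    stop("unknown badge tier: ", paste(setdiff(eco$badges, BADGE_TIERS),
                                       collapse = ", "), call. = FALSE)
  }
  has <- BADGE_TIERS %in% eco$badges
  if ((has[3] && !has[2]) || (has[2] && !has[1])) {
    stop("badge set must be downward closed (gold implies silver implies bronze)",
         call. = FALSE)
  }
  invisible(eco)
}

#' Badge rule: three increasing thresholds on a named metric
#'
#' @param metric name of the counted metric (e.g. `"levels_completed"`).
#' @param bronze,silver,gold strictly increasing positive integer thresholds.
#' @return A list of class `badge_rule`.
#' @examples
#' badge_rule("levels_completed", 4, 10, 26)
#' @export
badge_rule <- function(metric, bronze, silver, gold) {
  thr <- as.integer(c(bronze, silver, gold))
  if (any(is.na(thr)) || any(thr <= 0) || !all(diff(thr) > 0)) {
    stop("badge thresholds must be strictly increasing positive integers",
         call. = FALSE)
  }
  structure(list(metric = metric, bronze = thr[1], silver = thr[2],
                 gold = thr[3]), class = "badge_rule")
}

#' Award badges for a metric count
#'
#' A tier is held exactly when the count has reached its threshold; combined
#' with the monotone union against already-held badges this makes the
#' operation idempotent and badge sets monotone over a session.
#'
#' @param count current non-negative metric count.
#' @param rule a [badge_rule()].
#' @param economy an [economy_state()].
#' @return The updated `economy_state`.
#' @export
award_badges <- function(count, rule, economy) {
  stopifnot(inherits(rule, "badge_rule"), inherits(economy, "economy_state"),
            count >= 0)
  thr <- c(bronze = rule$bronze, silver = rule$silver, gold = rule$gold)
  earned <- BADGE_TIERS[count >= thr]
  economy$badges <- sort(unique(c(economy$badges, earned)))
  validate_economy(economy)
  economy
}

#' Buy an extra life at a doubling coin cost
#'
#' The first purchase costs 10 coins; every later purchase costs twice the
#' previous one (10, 20, 40, ...). With insufficient coins the purchase is
#' refused and the state is returned unchanged.
#'
#' @param economy an [economy_state()].
#' @param base_cost cost of the first purchase in coins.
#' @return A list with elements `economy`, `cost` (the price quoted) and
#'   `refused` (logical).
#' @export
purchase_life <- function(economy, base_cost = 10L) {
  stopifnot(inherits(economy, "economy_state"))
  cost <- as.integer(base_cost * 2^economy$paid_life_purchases)
  if (economy$coins < cost) {
    return(list(economy = economy, cost = cost, refused = TRUE))
  }
  economy$coins <- economy$coins - cost
  economy$lives <- economy$lives + 1L
  economy$paid_life_purchases <- economy$paid_life_purchases + 1L
  validate_economy(economy)
  list(economy = economy, cost = cost, refused = FALSE)
}

#' Spend a double jump
#'
#' Free double jumps are consumed first at no cost; afterwards each double
#' jump costs a flat 10 coins. Refused (state unchanged) when no free jump
#' remains and coins are short.
#'
#' @param economy an [economy_state()].
#' @param cost coin price of a paid double jump.
#' @return A list with `economy`, `cost` (0 when a free jump was used) and
#'   `refused`.
#' @export
purchase_double_jump <- function(economy, cost = 10L) {
  stopifnot(inherits(economy, "economy_state"))
  if (economy$free_double_jumps > 0L) {
    economy$free_double_jumps <- economy$free_double_jumps - 1L
    return(list(economy = economy, cost = 0L, refused = FALSE))
  }
  if (economy$coins < cost) {
    return(list(economy = economy, cost = as.integer(cost), refused = TRUE))
  }
  economy$coins <- economy$coins - as.integer(cost)
  validate_economy(economy)
  list(economy = economy, cost = as.integer(cost), refused = FALSE)
}

#' @export
print.economy_state <- function(x, ...) {
  cat(sprintf("<economy> points=%d coins=%d lives=%d free_dj=%d badges={%s}\n",
              x$points, x$coins, x$lives, x$free_double_jumps,
              paste(x$badges, collapse = ",")))
  invisible(x)
}
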