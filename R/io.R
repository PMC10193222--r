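#' Load an engine configuration
#'
#' YAML or JSON with a master seed, per-game parameter blocks (badge
#' thresholds, economy constants, staircase parameters, trick-game order)
#' and content-bank paths. Missing blocks fall back to the engine defaults;
#' badge thresholds are validated through [badge_rule()].
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return list of class `engine_config`.
#' @export
load_engine_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- default_engine_config()
  cfg <- utils::modifyList(defaults, cfg)
  for (g in names(cfg$badges)) {
    thr <- cfg$badges[[g]]
    badge_rule(g, thr[1], thr[2], thr[3]) # validates ordering
  }
  structure(cfg, class = "engine_config")
}

#' @rdname load_engine_config
#' @export
default_engine_config <- function() {
  list(schema_version = 1L,
       master_seed = 1L,
       badges = list(wsap = c(4L, 10L, 26L),
                     executive = c(6L, 15L, 39L),
                     attention = c(34L, 60L, 156L),
                     imagery = c(4L, 10L, 26L)),
       economy = list(exec_free_lives = 3L, exec_free_double_jumps = 5L,
                      life_base_cost = 10L, double_jump_cost = 10L,
                      attention_free_lives = 5L),
       staircase = list(up_acc = 0.9, down_acc = 0.6, t_step_ms = 1000L),
       trick_order = c("fifteen", "butterfly", "arc"))
}

#' Validate a content bank file
#'
#' Checks a bank against the per-game invariants and returns every violation
#' found: for the word-search bank, item counts, word/grid feasibility and
#' the decoy valence-to-answer contract; for the scenario bank, disjoint
#' non-empty completion lists; for the song bank, positive note counts; for
#' the stimulus pool, at least one positive and five negative ids. An empty
#' report means the bank loads cleanly.
#'
#' @param path bank file.
#' @param kind `"wsap"`, `"scenario"`, `"song"` or `"stimulus"`.
#' @return character vector of violations (length 0 when valid).
#' @export
validate_content_bank <- function(path,
                                  kind = c("wsap", "scenario", "song",
                                           "stimulus")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read bank file: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("unparsable bank file: ",
                                           conditionMessage(e), call. = FALSE))
  issues <- character()
  note <- function(...) issues <<- c(issues, sprintf(...))
  if (kind == "wsap") {
    items <- raw$items
    if (length(items) != 42L) note("expected 42 items, found %d", length(items))
    for (i in seq_along(items)) {
      it <- items[[i]]
      need <- c("sentence", "probe_word", "probe_valence")
      miss <- need[!need %in% names(it)]
      if (length(miss) > 0L) {
        note("item %d: missing fields %s", i, paste(miss, collapse = ", "))
        next
      }
      if (!it$probe_valence %in% c("positive", "negative")) {
        note("item %d: bad valence '%s'", i, it$probe_valence)
      }
      words <- sentence_words(it$sentence)
      if (length(words) == 0L) note("item %d: sentence has no words", i)
      if (length(words) > 0L && max(nchar(words)) > 8L) {
        note("item %d: word '%s' longer than the 8-cell grid line", i,
             words[which.max(nchar(words))])
      }
      if (!is.null(it$correct_answer)) {
        expect <- if (isTRUE(it$is_decoy)) {
          if (it$probe_valence == "negative") "yes" else "no"
        } else {
          if (it$probe_valence == "positive") "yes" else "no"
        }
        if (it$correct_answer != expect) {
          note("item %d: correct_answer '%s' violates the %s contract", i,
               it$correct_answer, if (isTRUE(it$is_decoy)) "decoy" else "item")
        }
      }
    }
  } else if (kind == "scenario") {
    scens <- raw$scenarios
    if (length(scens) != 20L) {
      note("expected 20 scenarios, found %d", length(scens))
    }
    for (i in seq_along(scens)) {
      s <- scens[[i]]
      ok <- tryCatch({
        scenario(s$part1, s$part2, unlist(s$positive1), unlist(s$negative1),
                 unlist(s$positive2), unlist(s$negative2))
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) note("scenario %d: %s", i, ok)
    }
  } else if (kind == "song") {
    songs <- raw$songs
    if (length(songs) != 20L) note("expected 20 songs, found %d", length(songs))
    for (i in seq_along(songs)) {
      s <- songs[[i]]
      if (is.null(s$n_notes) || s$n_notes < 1L) {
        note("song %d: note count must be >= 1", i)
      }
    }
  } else {
    if (length(raw$positive) < 1L) note("stimulus pool needs >= 1 positive id")
    if (length(raw$negative) < 5L) note("stimulus pool needs >= 5 negative ids")
    if (length(intersect(unlist(raw$positive), unlist(raw$negative))) > 0L) {
      note("stimulus ids appear with both valences")
    }
  }
  issues
}

#' Write demonstration fixtures
#'
#' Emits small valid content banks for all five games (including the
#' canonical example sentences), a default agent profile, and a demo config
#' into `output_dir`. Output is deterministic per seed, so repeated calls
#' with the same seed produce identical bytes.
#'
#' @param seed master seed stamped into the demo config.
#' @param output_dir writable directory.
#' @return Character vector of written file paths, invisibly.
#' @export
generate_fixtures <- function(seed, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir,
                  call. = FALSE)
  }
  src <- c(wsap_bank.json = "wsap_bank.json",
           scenario_bank.json = "scenario_bank.json",
           song_bank.json = "song_bank.json",
           stimulus_pool.json = "stimulus_pool.json")
  written <- character()
  for (f in src) {
    from <- system.file("extdata", f, package = "cbmgames")
    to <- file.path(output_dir, f)
    file.copy(from, to, overwrite = TRUE)
    written <- c(written, to)
  }
  profile_path <- file.path(output_dir, "agent_profile.json")
  jsonlite::write_json(list(skill = 0.9, interpretation_bias = 0.9,
                            rt_median_ms = 800, rt_sigma = 0.4,
                            persistence = 6, resilience = 2),
                       profile_path, auto_unbox = TRUE, pretty = TRUE)
  cfg <- default_engine_config()
  cfg$master_seed <- as.integer(seed)
  cfg_path <- file.path(output_dir, "engine_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(c(written, profile_path, cfg_path))
}

#' Export round-level executive-training data as CSV
#'
#' One row per logged `round_result` event with congruency, image valence,
#' circle color and correctness.
#'
#' @param log an [event_log()] from [run_exec_session()].
#' @param path output CSV path.
#' @return The data frame, invisibly.
#' @export
write_round_csv <- function(log, path) {
  ev <- log_events(log, "round_result")
  df <- data.frame(
    ts_ms = vapply(ev, function(e) e$ts_ms, 1L),
    congruency = vapply(ev, function(e) e$payload$congruency, ""),
    valence = vapply(ev, function(e) e$payload$valence, ""),
    color = vapply(ev, function(e) e$payload$color, ""),
    outcome = vapply(ev, function(e) e$payload$outcome, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a Likert feedback CSV
#'
#' Expects columns `user_id`, `game`, `aspect`, `rating_label`.
#'
#' @param path CSV path.
#' @return data frame ready for [analyze_feedback()].
#' @export
read_feedback_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("user_id", "game", "aspect", "rating_label")
  miss <- needed[!needed %in% names(df)]
  if (length(miss) > 0L) {
    stop("feedback CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
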