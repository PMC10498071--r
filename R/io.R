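LOG_COLUMNS <- c("index", "onset_s", "fixation_ms", "digit", "stim_class",
                 "mode", "response", "rt_ms", "outcome", "corrected")
SCHEMA_VERSION <- "1.0"

#' Write a session log to disk
#'
#' One CSV row per trial (columns `index`, `onset_s`, `fixation_ms`,
#' `digit`, `stim_class`, `mode`, `response`, `rt_ms`, `outcome`,
#' `corrected`) plus a JSON sidecar (`<path>.json` with the `.csv`
#' extension replaced) holding the configuration snapshot, the seed, the
#' responder metadata and a schema version.
#'
#' @param log An `msart_log`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "msart_log"))
  utils::write.csv(log$trials[, LOG_COLUMNS], path, row.names = FALSE, na = "")
  sidecar <- list(
    schema_version = SCHEMA_VERSION,
    config = unclass(log$config),
    responder = log$responder,
    final_state = unclass(log$final_state)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a session log from disk
#'
#' Validates the schema: the header must contain exactly the expected
#' columns, onsets must be strictly increasing, and the sidecar's schema
#' major version must match. Malformed input is rejected with a diagnostic
#' naming the offending column or row.
#'
#' @param path CSV path written by [write_session_log()].
#' @return An `msart_log`. Without a sidecar, the default configuration is
#'   assumed and the terminal mode state is reconstructed by replaying the
#'   outcomes.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("no such log file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty log file: ", path, call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(LOG_COLUMNS, names(tr))
  if (length(missing_cols)) {
    stop("log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tr), LOG_COLUMNS)
  if (length(extra)) {
    stop("log schema error: unexpected column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (nrow(tr) == 0L) stop("log contains a header but no trials: ", path, call. = FALSE)
  bad <- which(diff(tr$onset_s) <= 0)
  if (length(bad)) {
    stop("log schema error: onsets not strictly increasing at row(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  tr$corrected <- as.logical(tr$corrected)
  tr$rt_ms <- as.numeric(tr$rt_ms)

  sc <- sidecar_path(path)
  cfg <- session_config()
  meta <- list(label = "unknown")
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    major <- strsplit(as.character(side$schema_version), ".", fixed = TRUE)[[1L]][1L]
    if (major != strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1L]][1L]) {
      stop("unsupported log schema version: ", side$schema_version, call. = FALSE)
    }
    cfg <- do.call(session_config, side$config)
    if (!is.null(side$responder)) meta <- side$responder
  }
  new_session_log(cfg, tr, meta, replay_final_state(tr))
}

replay_final_state <- function(tr) {
  s <- mode_state()
  for (i in seq_len(nrow(tr))) {
    out <- tr$outcome[i]
    if (out == "nogo_commission") s <- next_mode(s, "nogo_commission")
    else if (out == "nogo_correct") s <- next_mode(s, "nogo_correct")
    if (tr$corrected[i]) s <- next_mode(s, "b_press")
  }
  s$deepest_mode <- max(tr$mode)
  s
}

#' Read a session configuration from a YAML or JSON file
#'
#' Any subset of [session_config()] fields may be given; the rest keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `msart_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(session_config)))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(session_config, vals)
}

#' Write per-session and per-window metric tables
#'
#' `write_metrics_csv()` writes one row per scored session;
#' `write_windows_csv()` writes the long format consumed by the
#' inferential layer (columns `session_id`, `window`, `metric`, `value`).
#'
#' @param metrics A named list of `msart_metrics` (names become
#'   `session_id`) or a single `msart_metrics`.
#' @param windows A named list of [window_metrics()] data frames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "msart_metrics")) metrics <- list(session = metrics)
  rows <- Map(function(id, m) cbind(data.frame(session_id = id), as.data.frame(m)),
              names(metrics), metrics)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_windows_csv <- function(windows, path) {
  long <- do.call(rbind, Map(function(id, wm) {
    metric_cols <- setdiff(names(wm), c("window", "n_go", "n_nogo"))
    do.call(rbind, lapply(metric_cols, function(mc) {
      data.frame(session_id = id, window = wm$window, metric = mc,
                 value = wm[[mc]], stringsAsFactors = FALSE)
    }))
  }, names(windows), windows))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Generate the reference fixture set
#'
#' Writes four deterministic logs: (a) `worked_example.csv`, a scripted
#' session with exactly five consecutive no-go commissions followed by a
#' correct withhold (deepest mode 6, moderate); (b) `perfect.csv`, an
#' error-free session that never leaves mode 1; (c) one full-length session
#' per severity preset (`mild.csv`, `moderate.csv`, `severe.csv`); (d)
#' `toy_exclusion.csv`, a hand-built trial table exercising all three
#' pre-no-go RT exclusion rules, whose retained sets are known by
#' enumeration.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the CSV paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  cfg_short <- session_config(session_duration = 400, rng_seed = seed)
  worked <- run_session(cfg_short, scripted_responder(rep("press", 5)))
  paths["worked_example"] <- file.path(out_dir, "worked_example.csv")
  write_session_log(worked, paths[["worked_example"]])

  perfect <- run_session(cfg_short, perfect_responder())
  paths["perfect"] <- file.path(out_dir, "perfect.csv")
  write_session_log(perfect, paths[["perfect"]])

  for (lv in c("mild", "moderate", "severe")) {
    log <- run_session(session_config(rng_seed = seed + match(lv, c("mild", "moderate", "severe"))),
                       markov_responder(responder_preset(lv)))
    paths[lv] <- file.path(out_dir, paste0(lv, ".csv"))
    write_session_log(log, paths[[lv]])
  }

  paths["toy_exclusion"] <- file.path(out_dir, "toy_exclusion.csv")
  write_session_log(toy_exclusion_log(), paths[["toy_exclusion"]])
  paths
}

#' Hand-built log exercising the pre-no-go exclusion rules
#'
#' Trial sequence (G = go, O = omitted go, N = no-go), one block per no-go:
#' `G G G G N | G G G G N | G G G G N | G G N | G O G G N | G G G G N`.
#' Go RTs in block b are 100 b + 10, 100 b + 20, ... The first two no-gos
#' are excluded as session-initial, the fourth has only two intervening go
#' trials, the fifth block contains an omission; only the third set
#' (RTs 310, 320, 330, 340) and the sixth (610, 620, 630, 640) are
#' retained.
#'
#' @return An `msart_log`.
#' @export
toy_exclusion_log <- function() {
  blocks <- list(
    c("G", "G", "G", "G", "N"),
    c("G", "G", "G", "G", "N"),
    c("G", "G", "G", "G", "N"),
    c("G", "G", "N"),
    c("G", "O", "G", "G", "N"),
    c("G", "G", "G", "G", "N")
  )
  sym <- unlist(blocks)
  n <- length(sym)
  block <- rep(seq_along(blocks), lengths(blocks))
  pos_in_block <- unlist(lapply(lengths(blocks), seq_len))
  rt <- ifelse(sym == "G", 100 * block + 10 * pos_in_block, NA_real_)
  trials <- data.frame(
    index = seq_len(n),
    onset_s = seq_len(n) * 1.5,
    fixation_ms = 1000L,
    digit = ifelse(sym == "N", 3L, 5L),
    stim_class = ifelse(sym == "N", "nogo", "go"),
    mode = 1L,
    response = ifelse(sym == "G", "press", "withhold"),
    rt_ms = ifelse(sym == "G", rt, NA_real_),
    outcome = ifelse(sym == "N", "nogo_correct",
                     ifelse(sym == "O", "go_omission", "go_correct")),
    corrected = FALSE,
    stringsAsFactors = FALSE
  )
  cfg <- session_config(session_duration = ceiling(max(trials$onset_s)) + 1)
  new_session_log(cfg, trials, list(label = "hand_built"), replay_final_state(trials))
}
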