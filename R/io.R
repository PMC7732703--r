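# Plain-text serialisation: model specs as a YAML config plus CSV matrix
# payloads (17 significant digits, so doubles round-trip exactly), and trial
# traces as tidy long-format CSV or JSON.

# write a numeric matrix as CSV with exact double round-trip
.write_matrix_csv <- function(M, path) {
  M <- as.matrix(M)
  txt <- apply(M, 1L, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(txt, path)
}

.read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("matrix file missing: %s", path), call. = FALSE)
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  M <- do.call(rbind, lapply(rows, as.numeric))
  if (any(!is.finite(M))) stop(sprintf("non-numeric entry in %s", path), call. = FALSE)
  M
}

#' Save a generative model as a plain-text spec
#'
#' Writes `model.yaml` (scalars: horizon, gamma, action labels, policies,
#' preference target, likelihood mode) plus CSV payloads (`likelihood.csv`,
#' `counts_prior.csv`, one `B_<action>.csv` per action, `D.csv`, `logC.csv`)
#' into `dir`. CSVs carry 17 significant digits so counts round-trip
#' bitwise.
#'
#' @param model A [generative_model()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model_spec <- function(model, dir) {
  stopifnot(inherits(model, "gen_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lik <- model$likelihood
  cfg <- list(
    horizon = model$policies$horizon,
    gamma = model$gamma,
    actions = as.list(model$transitions$actions),
    likelihood_mode = lik$mode,
    preference_target = model$preferences$target,
    policies = apply(model$policies$policies, 1L, paste, collapse = " "),
    policy_prior = model$policies$prior
  )
  yaml::write_yaml(cfg, file.path(dir, "model.yaml"))
  if (lik$mode == "point") {
    .write_matrix_csv(lik$probs, file.path(dir, "likelihood.csv"))
  } else {
    .write_matrix_csv(lik$counts, file.path(dir, "likelihood.csv"))
    .write_matrix_csv(lik$counts_prior, file.path(dir, "counts_prior.csv"))
  }
  for (u in model$transitions$actions) {
    .write_matrix_csv(model$transitions$B[[u]], file.path(dir, paste0("B_", u, ".csv")))
  }
  .write_matrix_csv(matrix(model$D, nrow = 1L), file.path(dir, "D.csv"))
  logC <- do.call(rbind, model$preferences$logC)
  .write_matrix_csv(logC, file.path(dir, "logC.csv"))
  invisible(dir)
}

#' Load a generative model from a plain-text spec
#'
#' Reads the files written by [save_model_spec()], validates every structural
#' invariant (matrices are never silently renormalised) and returns the
#' model. Errors name the offending file or key.
#'
#' @param dir Directory containing `model.yaml` and its CSV payloads.
#' @return A validated [generative_model()].
#' @export
load_model_spec <- function(dir) {
  cfg_path <- file.path(dir, "model.yaml")
  if (!file.exists(cfg_path)) stop(sprintf("missing config: %s", cfg_path), call. = FALSE)
  cfg <- yaml::read_yaml(cfg_path)
  for (key in c("horizon", "actions", "likelihood_mode", "preference_target",
                "policies")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("model.yaml: missing key '%s'", key), call. = FALSE)
    }
  }
  if (!is.numeric(cfg$horizon) || cfg$horizon < 1) {
    stop("model.yaml: horizon must be a positive integer", call. = FALSE)
  }
  gamma <- if (is.null(cfg$gamma)) 16 else cfg$gamma
  actions <- unlist(cfg$actions)
  lik <- if (identical(cfg$likelihood_mode, "point")) {
    likelihood_belief(probs = .read_matrix_csv(file.path(dir, "likelihood.csv")))
  } else {
    counts <- .read_matrix_csv(file.path(dir, "likelihood.csv"))
    prior_path <- file.path(dir, "counts_prior.csv")
    likelihood_belief(counts = counts,
                      counts_prior = if (file.exists(prior_path)) {
                        .read_matrix_csv(prior_path)
                      } else counts)
  }
  B <- lapply(actions, function(u) .read_matrix_csv(file.path(dir, paste0("B_", u, ".csv"))))
  names(B) <- actions
  D <- as.numeric(.read_matrix_csv(file.path(dir, "D.csv")))
  logC <- .read_matrix_csv(file.path(dir, "logC.csv"))
  pref <- preferences(lapply(seq_len(nrow(logC)), function(i) logC[i, ]),
                      target = cfg$preference_target)
  pol_rows <- strsplit(unlist(cfg$policies), " ", fixed = TRUE)
  pol <- do.call(rbind, pol_rows)
  if (as.integer(cfg$horizon) == 1L) pol <- matrix(character(0), 1L, 0L)
  pols <- policy_space(pol, as.integer(cfg$horizon),
                       prior = if (is.null(cfg$policy_prior)) NULL else unlist(cfg$policy_prior),
                       actions = actions)
  generative_model(lik, transition_model(B), D, pref, pols, gamma)
}

#' Export a trial record as a tidy table
#'
#' Long format, one row per recorded scalar, with deterministic column order
#' `epoch, kind, policy, state, value`. Kinds: `observation`, `action`
#' (value is the action's index in the action set), `F`, `G`, `q_pi`
#' (per policy), `s` (policy-independent beliefs, per state), and `v`
#' (final per-policy potentials at the last epoch) when `include_v = TRUE`.
#'
#' @param record A [run_trial()] record.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @param include_v Also export the final potentials `v` per policy.
#' @return `path`, invisibly.
#' @export
export_trace <- function(record, path, format = c("csv", "json"),
                         include_v = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(record, "trial_record"))
  T_len <- length(record$observations)
  n_pi <- ncol(record$q_pi)
  actions <- record$model$transitions$actions
  rows <- list()
  add <- function(epoch, kind, policy, state, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      epoch = epoch, kind = kind, policy = policy, state = state,
      value = value, stringsAsFactors = FALSE)
  }
  for (t in seq_len(T_len)) {
    add(t, "observation", NA_integer_, NA_integer_, record$observations[t])
    if (t < T_len) {
      add(t, "action", NA_integer_, NA_integer_, match(record$actions[t], actions))
    }
    add(t, "F", seq_len(n_pi), NA_integer_, record$F[t, ])
    add(t, "G", seq_len(n_pi), NA_integer_, record$G[t, ])
    add(t, "q_pi", seq_len(n_pi), NA_integer_, record$q_pi[t, ])
    add(t, "s", NA_integer_, seq_len(ncol(record$states)), record$states[t, ])
  }
  if (include_v) {
    for (p in seq_len(n_pi)) {
      v <- record$beliefs$v[[p]]
      for (t in seq_len(nrow(v))) {
        add(t, "v", p, seq_len(ncol(v)), v[t, ])
      }
    }
  }
  df <- do.call(rbind, rows)
  if (format == "csv") {
    df$value <- sprintf("%.17g", df$value)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "columns", na = "null",
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read back an exported trace
#'
#' @param path File written by [export_trace()].
#' @param format `"csv"` or `"json"`.
#' @return A data frame with columns `epoch, kind, policy, state, value`.
#' @export
read_trace <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
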