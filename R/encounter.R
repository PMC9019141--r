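#' Observation codes
#'
#' Encounter histories use the integer codes 1 = observed alive,
#' 2 = recovered dead, 3 = neither observed alive nor recovered.
#'
#' @format Named integer vector of length 3.
#' @export
obs_codes <- c(SEEN_ALIVE = 1L, RECOVERED_DEAD = 2L, NOT_OBSERVED = 3L)

#' Construct a single encounter history
#'
#' @param individual_id Character id, unique within a set.
#' @param first_capture Occasion index of first capture (1-based).
#' @param obs Integer vector of observation codes over occasions
#'   `first_capture..n_occasions`, or over `1..n_occasions` (entries before
#'   first capture must then be 3 / NOT_OBSERVED).
#' @param n_occasions Total number of occasions (study horizon).
#' @return An `encounter_history`: list with `individual_id`,
#'   `first_capture` and `obs`, where `obs` always spans occasions
#'   `1..n_occasions` with NOT_OBSERVED padding before first capture.
#' @export
encounter_history <- function(individual_id, first_capture, obs, n_occasions) {
  first_capture <- as.integer(first_capture)
  n_occasions <- as.integer(n_occasions)
  obs <- as.integer(obs)
  if (length(obs) == n_occasions - first_capture + 1L) {
    obs <- c(rep(obs_codes[["NOT_OBSERVED"]], first_capture - 1L), obs)
  }
  if (length(obs) != n_occasions) {
    stop(sprintf("obs for '%s' has length %d, expected %d (or %d from first capture)",
                 individual_id, length(obs), n_occasions,
                 n_occasions - first_capture + 1L), call. = FALSE)
  }
  structure(
    list(individual_id = as.character(individual_id),
         first_capture = first_capture, obs = obs),
    class = "encounter_history"
  )
}

#' Validate a single encounter history
#'
#' Checks the structural invariants of a live-recapture/dead-recovery
#' history: valid codes, first capture observed alive, nothing observed
#' before first capture, at most one dead recovery, and nothing but
#' NOT_OBSERVED after a recovery (the recovered state is followed by the
#' absorbing, never-observed dead state).
#'
#' @param h An `encounter_history`.
#' @return Character vector of violations; empty if the history is valid.
#' @export
validate_history <- function(h) {
  v <- character(0)
  id <- h$individual_id
  obs <- h$obs
  fc <- h$first_capture
  bad <- which(!obs %in% obs_codes)
  if (length(bad)) {
    v <- c(v, sprintf("%s: invalid code %s at occasion %d", id, obs[bad], bad))
    return(v)
  }
  if (fc < 1L || fc > length(obs)) {
    return(c(v, sprintf("%s: first_capture %d outside 1..%d", id, fc, length(obs))))
  }
  if (obs[fc] != obs_codes[["SEEN_ALIVE"]]) {
    v <- c(v, sprintf("%s: occasion %d (first capture) is not SEEN_ALIVE", id, fc))
  }
  if (fc > 1L && any(obs[seq_len(fc - 1L)] != obs_codes[["NOT_OBSERVED"]])) {
    v <- c(v, sprintf("%s: observation before first capture (occasion %d)",
                      id, which(obs[seq_len(fc - 1L)] != obs_codes[["NOT_OBSERVED"]])[1L]))
  }
  rec <- which(obs == obs_codes[["RECOVERED_DEAD"]])
  if (length(rec) > 1L) {
    v <- c(v, sprintf("%s: %d dead recoveries (at most one allowed), second at occasion %d",
                      id, length(rec), rec[2L]))
  }
  if (length(rec) >= 1L && rec[1L] < length(obs)) {
    after <- obs[(rec[1L] + 1L):length(obs)]
    off <- which(after == obs_codes[["SEEN_ALIVE"]])  # extra recoveries counted above
    if (length(off)) {
      v <- c(v, sprintf("%s: live observation after dead recovery at occasion %d",
                        id, rec[1L] + off[1L]))
    }
  }
  v
}

#' Assemble a set of encounter histories
#'
#' @param histories List of `encounter_history` objects sharing a horizon.
#' @param calendar The `occasion_calendar`; its horizon must be at least
#'   `n_occasions`.
#' @param n_occasions Study horizon (number of occasions actually
#'   observed); defaults to the calendar's full horizon.
#' @param validate Check all history invariants (default TRUE).
#' @return An `encounter_history_set`: list with `id`, `first_capture`,
#'   `obs` (n x n_occasions integer matrix), `n_occasions`, `calendar`.
#' @export
encounter_history_set <- function(histories, calendar,
                                  n_occasions = calendar$n_occasions,
                                  validate = TRUE) {
  stopifnot(inherits(calendar, "occasion_calendar"))
  n_occasions <- as.integer(n_occasions)
  if (n_occasions > calendar$n_occasions) {
    stop("n_occasions exceeds the calendar horizon", call. = FALSE)
  }
  n <- length(histories)
  id <- vapply(histories, `[[`, character(1), "individual_id")
  if (anyDuplicated(id)) {
    stop(sprintf("duplicated individual_id: %s", id[duplicated(id)][1L]),
         call. = FALSE)
  }
  obs <- matrix(obs_codes[["NOT_OBSERVED"]], nrow = n, ncol = n_occasions,
                dimnames = list(id, NULL))
  fc <- integer(n)
  for (i in seq_len(n)) {
    h <- histories[[i]]
    if (length(h$obs) != n_occasions) {
      stop(sprintf("history '%s' spans %d occasions, set expects %d",
                   h$individual_id, length(h$obs), n_occasions), call. = FALSE)
    }
    if (validate) {
      v <- validate_history(h)
      if (length(v)) stop(paste(v, collapse = "; "), call. = FALSE)
    }
    obs[i, ] <- h$obs
    fc[i] <- h$first_capture
  }
  structure(
    list(id = id, first_capture = fc, obs = obs,
         n_occasions = n_occasions, calendar = calendar),
    class = "encounter_history_set"
  )
}

#' @export
print.encounter_history_set <- function(x, ...) {
  cat(sprintf("Encounter histories: %d individuals x %d biweekly occasions\n",
              length(x$id), x$n_occasions))
  cat(sprintf("  seen alive: %d, recovered dead: %d, not observed: %d\n",
              sum(x$obs == 1L), sum(x$obs == 2L), sum(x$obs == 3L)))
  invisible(x)
}

#' Extract one history from a set
#'
#' @param set An `encounter_history_set`.
#' @param i Row index or individual id.
#' @return An `encounter_history`.
#' @export
get_history <- function(set, i) {
  if (is.character(i)) i <- match(i, set$id)
  encounter_history(set$id[i], set$first_capture[i], set$obs[i, ],
                    set$n_occasions)
}

#' Read encounter histories from CSV
#'
#' Expects the dialect `id,first_capture,occ_1,...,occ_T` with integer
#' codes 1/2/3 (see [obs_codes]). An empty file (header only) yields an
#' empty set.
#'
#' @param path CSV file path.
#' @param calendar The `occasion_calendar` the histories live on.
#' @return A validated `encounter_history_set`.
#' @export
read_histories <- function(path, calendar) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  occ_cols <- grep("^occ_", names(df))
  if (ncol(df) < 2L || names(df)[1L] != "id" || names(df)[2L] != "first_capture") {
    stop("expected header id,first_capture,occ_1,...,occ_T", call. = FALSE)
  }
  n_occ <- length(occ_cols)
  histories <- lapply(seq_len(nrow(df)), function(i) {
    codes <- as.integer(unlist(df[i, occ_cols]))
    bad <- which(!codes %in% obs_codes)
    if (length(bad)) {
      stop(sprintf("row %d (id %s): unknown observation code '%s' in column %s",
                   i, df$id[i], df[i, occ_cols[bad[1L]]],
                   names(df)[occ_cols[bad[1L]]]), call. = FALSE)
    }
    encounter_history(df$id[i], df$first_capture[i], codes, n_occ)
  })
  if (nrow(df) == 0L) {
    n_occ <- if (n_occ > 0L) n_occ else calendar$n_occasions
  }
  encounter_history_set(histories, calendar, n_occasions = n_occ)
}

#' Write encounter histories to CSV
#'
#' Inverse of [read_histories()]: `read_histories(write_histories(s))`
#' reproduces `s` exactly.
#'
#' @param set An `encounter_history_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histories <- function(set, path) {
  df <- data.frame(id = set$id, first_capture = set$first_capture,
                   stringsAsFactors = FALSE)
  obs <- as.data.frame(set$obs)
  names(obs) <- paste0("occ_", seq_len(set$n_occasions))
  utils::write.csv(cbind(df, obs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
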