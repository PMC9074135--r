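# Replica-exchange utilities: geometric temperature ladders, exchange-log
# statistics, the Metropolis exchange criterion, and synthetic exchange
# logs with a known acceptance fraction.
#
# Exchange-log format (plain text): one record per line,
#   attempt i j accepted(0/1)
# with (i, j) a neighbouring replica pair on the ladder.

.KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

#' Geometric (exponentially spaced) replica temperature ladder
#'
#' `T_i = t_min * (t_max / t_min)^(i / (n - 1))`, i = 0..n-1, so that
#' log-temperatures are equally spaced.
#'
#' @param t_min,t_max ladder endpoints in K (defaults 270 and 615).
#' @param n number of replicas (>= 2).
#' @return strictly increasing numeric vector of length `n`.
#' @export
temperature_ladder <- function(t_min = 270, t_max = 615, n = 10) {
  if (n < 2) stop("a ladder needs at least 2 replicas")
  if (!(t_max > t_min && t_min > 0)) stop("need t_max > t_min > 0")
  t_min * (t_max / t_min)^(seq(0, n - 1) / (n - 1))
}

#' Construct / read / write an exchange log
#'
#' @param attempt integer attempt indices.
#' @param i,j neighbouring replica pair of each attempt (j = i + 1).
#' @param accepted logical acceptance flags.
#' @return data.frame of class `exchange_log`.
#' @export
exchange_log <- function(attempt, i, j, accepted) {
  if (!all(j == i + 1)) stop("exchange pairs must be ladder neighbours")
  structure(data.frame(attempt = as.integer(attempt), i = as.integer(i),
                       j = as.integer(j), accepted = as.logical(accepted)),
            class = c("exchange_log", "data.frame"))
}

#' @rdname exchange_log
#' @param path file path for plain-text log I/O.
#' @export
read_exchange_log <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("attempt", "i", "j", "accepted"))
  exchange_log(d$attempt, d$i, d$j, d$accepted == 1)
}

#' @rdname exchange_log
#' @param log an `exchange_log`.
#' @export
write_exchange_log <- function(log, path) {
  writeLines(sprintf("%d %d %d %d", log$attempt, log$i, log$j,
                     as.integer(log$accepted)), path)
  invisible(path)
}

#' Acceptance fractions of an exchange log
#'
#' @param log an `exchange_log` (or data.frame with `i`, `j`, `accepted`).
#' @return list with `overall` (accepted / attempted) and `per_pair`
#'   (data.frame: pair, attempts, accepted, fraction).
#' @export
exchange_frequency <- function(log) {
  if (!nrow(log)) stop("empty exchange log")
  key <- paste0(log$i, "-", log$j)
  sp <- split(log$accepted, key)
  per <- data.frame(pair = names(sp),
                    attempts = vapply(sp, length, 1L),
                    accepted = vapply(sp, sum, 1L))
  per$fraction <- per$accepted / per$attempts
  per <- per[order(as.integer(sub("-.*", "", per$pair))), ]
  rownames(per) <- NULL
  list(overall = mean(log$accepted), per_pair = per)
}

#' Metropolis exchange probability between two replicas
#'
#' `p = min(1, exp((1/kT_i - 1/kT_j) * (E_i - E_j)))` with k in
#' kcal/(mol K), the standard temperature-REMD criterion.
#'
#' @param e_i,e_j potential energies (kcal/mol).
#' @param t_i,t_j replica temperatures (K, > 0).
#' @return acceptance probability in `[0, 1]`.
#' @export
metropolis_exchange_p <- function(e_i, e_j, t_i, t_j) {
  if (any(c(t_i, t_j) <= 0)) stop("temperatures must be positive")
  delta <- (1 / (.KB_KCAL * t_i) - 1 / (.KB_KCAL * t_j)) * (e_i - e_j)
  pmin(1, exp(delta))
}

#' Ladder member closest to a target temperature
#'
#' @param ladder increasing temperature vector.
#' @param target target temperature in K (default 300).
#' @return list with `index` and `temperature`; equidistant ties resolve to
#'   the lower temperature.
#' @export
nearest_temperature <- function(ladder, target = 300) {
  dd <- abs(ladder - target)
  idx <- which(dd == min(dd))[1]       # ties: lower temperature first
  list(index = idx, temperature = ladder[idx])
}

#' Synthesize an exchange log with an exact acceptance fraction
#'
#' Attempts follow the alternating neighbour-pair schedule (rounds over the
#' even-offset pairs 1-2, 3-4, ... alternating with the odd-offset pairs
#' 2-3, 4-5, ...); exactly `round(acceptance * n_attempts)` attempts are
#' accepted, their positions drawn by a seeded shuffle so the log is
#' reproducible.
#'
#' @param n_replicas number of replicas (>= 2).
#' @param n_attempts total number of attempt records.
#' @param acceptance target acceptance fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an [exchange_log()].
#' @export
synth_exchange_log <- function(n_replicas, n_attempts, acceptance,
                               seed = 1L) {
  if (n_replicas < 2) stop("need at least 2 replicas")
  if (acceptance < 0 || acceptance > 1) stop("acceptance must be in [0, 1]")
  even <- seq(1, n_replicas - 1, by = 2)
  odd <- if (n_replicas > 2) seq(2, n_replicas - 1, by = 2) else even
  sched <- integer(0)
  round_id <- 0L
  while (length(sched) < n_attempts) {
    sched <- c(sched, if (round_id %% 2 == 0) even else odd)
    round_id <- round_id + 1L
  }
  sched <- sched[seq_len(n_attempts)]
  n_acc <- round(acceptance * n_attempts)
  flags <- rep(FALSE, n_attempts)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  flags[sample.int(n_attempts, n_acc)] <- TRUE
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  exchange_log(seq_len(n_attempts), sched, sched + 1L, flags)
}
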