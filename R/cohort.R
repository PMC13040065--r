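#' Cohort configuration for synthetic roster generation
#'
#' Describes a multi-site longitudinal cohort by the counts that drive the
#' study's exclusion cascade: enrolled fetuses, missing postnatal follow-up,
#' severe morbidity, fetuses with at least one scan in the 18-27 week window,
#' and fetuses excluded for low 2-year neurodevelopmental scores.  The
#' defaults reproduce the published cohort: 4321 enrolled, 681 missing
#' follow-up, 84 severe morbidity, 2906 scanned in-window, 101 low-score.
#'
#' @param n_enrolled fetuses enrolled.
#' @param n_missing_followup fetuses lacking 2-year follow-up.
#' @param n_severe_morbidity fetuses with severe morbidity.
#' @param n_with_scan_in_window eligible fetuses with >= 1 scan at 18-27 weeks.
#' @param n_low_score_excluded scanned fetuses excluded for low 2-year scores.
#' @param site_proportions named fractions summing to 1; defaults are the
#'   published per-site contributions, renormalised.
#' @param seed integer seed; all roster randomness flows from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_enrolled = 4321L,
                          n_missing_followup = 681L,
                          n_severe_morbidity = 84L,
                          n_with_scan_in_window = 2906L,
                          n_low_score_excluded = 101L,
                          site_proportions = default_site_proportions(),
                          seed = 1L) {
  cfg <- list(n_enrolled = as.integer(n_enrolled),
              n_missing_followup = as.integer(n_missing_followup),
              n_severe_morbidity = as.integer(n_severe_morbidity),
              n_with_scan_in_window = as.integer(n_with_scan_in_window),
              n_low_score_excluded = as.integer(n_low_score_excluded),
              site_proportions = site_proportions,
              seed = as.integer(seed))
  counts <- unlist(cfg[1:5])
  abort_if(any(counts < 0), "cohort counts must be non-negative")
  n_excl <- cfg$n_missing_followup + cfg$n_severe_morbidity
  abort_if(n_excl > cfg$n_enrolled,
           "follow-up and morbidity exclusions exceed enrolment")
  abort_if(cfg$n_with_scan_in_window > cfg$n_enrolled - n_excl,
           "more scanned fetuses than eligible fetuses")
  abort_if(cfg$n_low_score_excluded > cfg$n_with_scan_in_window,
           "more low-score exclusions than scanned fetuses")
  abort_if(abs(sum(site_proportions) - 1) > 1e-9,
           "site proportions must sum to 1")
  structure(cfg, class = "cohort_config")
}

#' Published per-site cohort contributions
#'
#' Fractions of fetuses contributed by each study site (Turin, Oxford,
#' Pelotas, Nairobi, Muscat, Beijing, Nagpur), renormalised to sum to one.
#'
#' @return named numeric vector.
#' @export
default_site_proportions <- function() {
  p <- c(Turin = 0.112, Oxford = 0.114, Pelotas = 0.118, Nairobi = 0.142,
         Muscat = 0.156, Beijing = 0.171, Nagpur = 0.188)
  p / sum(p)
}

# protocol visit schedule: first visit GA ~ U[14, 18], subsequent visits at
# +5 +/- 1 weeks (uniform jitter), truncated at 42 weeks
protocol_schedule <- function(n) {
  lapply(seq_len(n), function(i) {
    gas <- runif(1, 14, 18)
    repeat {
      nxt <- gas[length(gas)] + 5 + runif(1, -1, 1)
      if (nxt > 42) break
      gas <- c(gas, nxt)
    }
    gas
  })
}

#' Build a synthetic cohort roster
#'
#' Generates one record per enrolled fetus with site, sex, exclusion flags
#' and a longitudinal scan schedule, such that every flagged category count
#' equals its configured count exactly.  Flags are disjoint: follow-up and
#' morbidity exclusions are assigned first; among the remaining eligible
#' fetuses, exactly `n_with_scan_in_window` keep at least one scan at 18-27
#' weeks (the others have their in-window visits removed, emulating missed
#' visits), and the low-score flag is assigned among those scanned fetuses.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_roster` data.frame with columns fetus_id, site, sex,
#'   followup_missing, severe_morbidity, low_score and a list-column
#'   scan_gas of visit gestational ages (weeks, sorted).
#' @export
build_roster <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_enrolled
  set.seed(config$seed)
  if (n == 0L) {
    out <- data.frame(fetus_id = character(), site = character(),
                      sex = character(), followup_missing = logical(),
                      severe_morbidity = logical(), low_score = logical(),
                      stringsAsFactors = FALSE)
    out$scan_gas <- list()
    class(out) <- c("cohort_roster", "data.frame")
    return(out)
  }
  site <- sample(names(config$site_proportions), n, replace = TRUE,
                 prob = config$site_proportions)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  scan_gas <- protocol_schedule(n)

  followup_missing <- severe_morbidity <- low_score <- rep(FALSE, n)
  excl <- sample.int(n, config$n_missing_followup + config$n_severe_morbidity)
  followup_missing[excl[seq_len(config$n_missing_followup)]] <- TRUE
  severe_morbidity[setdiff(excl, excl[seq_len(config$n_missing_followup)])] <- TRUE

  eligible <- which(!followup_missing & !severe_morbidity)
  scanned <- eligible[sample.int(length(eligible), config$n_with_scan_in_window)]
  not_scanned <- setdiff(eligible, scanned)
  # emulate missed in-window visits for the non-scanned eligible fetuses
  scan_gas[not_scanned] <- lapply(scan_gas[not_scanned],
                                  function(g) g[g < 18 | g >= 27])
  low_score[scanned[sample.int(length(scanned),
                               config$n_low_score_excluded)]] <- TRUE

  out <- data.frame(fetus_id = sprintf("F%05d", seq_len(n)),
                    site = site, sex = sex,
                    followup_missing = followup_missing,
                    severe_morbidity = severe_morbidity,
                    low_score = low_score, stringsAsFactors = FALSE)
  out$scan_gas <- lapply(scan_gas, sort)
  class(out) <- c("cohort_roster", "data.frame")
  out
}

#' Apply the cohort exclusion cascade
#'
#' Stages, in order: drop fetuses with missing follow-up; drop severe
#' morbidity; keep only fetuses with at least one scan at 18-27 weeks
#' (18 <= GA < 27); drop low-score fetuses.  With the published counts the
#' survivor sequence is 3640, 3556, 2906, 2805.
#'
#' @param roster a roster from [build_roster()].
#' @return list with `roster` (the survivors) and `stage_counts`, a named
#'   vector of survivor counts after each stage (preceded by `enrolled`).
#' @export
apply_exclusion_cascade <- function(roster) {
  has_window_scan <- vapply(roster$scan_gas,
                            function(g) any(g >= 18 & g < 27), logical(1))
  s1 <- !roster$followup_missing
  s2 <- s1 & !roster$severe_morbidity
  s3 <- s2 & has_window_scan
  s4 <- s3 & !roster$low_score
  counts <- c(enrolled = nrow(roster),
              after_followup = sum(s1),
              after_morbidity = sum(s2),
              with_scan_in_window = sum(s3),
              final = sum(s4))
  list(roster = roster[s4, , drop = FALSE], stage_counts = counts)
}

#' Write / read a roster as CSV
#'
#' The scan schedule list-column is serialised as a semicolon-separated
#' string of gestational ages.
#'
#' @param roster a cohort roster.
#' @param path file path.
#' @return `read_roster` returns the roster; `write_roster` the path,
#'   invisibly.
#' @export
write_roster <- function(roster, path) {
  flat <- as.data.frame(roster[setdiff(names(roster), "scan_gas")])
  flat$scan_gas <- vapply(roster$scan_gas,
                          function(g) paste(sprintf("%.6f", g), collapse = ";"),
                          character(1))
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  flat$scan_gas <- lapply(strsplit(as.character(flat$scan_gas), ";"),
                          function(s) as.numeric(s[nzchar(s)]))
  class(flat) <- c("cohort_roster", "data.frame")
  flat
}
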