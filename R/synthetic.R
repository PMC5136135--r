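# Synthetic data: individual fish records with exactly the statistical
# structure the model assumes, for parameter-recovery and end-to-end tests.

#' Canonical sampling months
#'
#' The six monthly samples of the northeast Florida lionfish programme
#' (April 2014 - January 2015) with their sample sizes; sampling is placed
#' mid-month. January belongs to the same sampling series as the 2014
#' months, which the `year` column makes explicit.
#'
#' @return A tibble with columns `label`, `year`, `month`, `sample_time`,
#'   `n`.
#' @export
study_months <- function() {
  m <- c(4L, 7L, 8L, 10L, 11L, 1L)
  y <- c(2014L, 2014L, 2014L, 2014L, 2014L, 2015L)
  tibble::tibble(
    label = sprintf("%d-%02d", y, m),
    year = y, month = m,
    sample_time = year_fraction(m, 15),
    n = c(850L, 33L, 1102L, 53L, 41L, 58L)
  )
}

#' Canonical proportions-at-age
#'
#' Monthly proportions of age classes 0-3 estimated for the northeast
#' Florida population, used as the generating age structure of the
#' canonical synthetic scenario.
#'
#' @return A long tibble with columns `label`, `age`, `p`.
#' @export
study_proportions <- function() {
  labels <- study_months()$label
  P <- rbind(
    c(0.37, 0.62, 0.00, 0.02),  # April
    c(0.00, 0.63, 0.37, 0.00),  # July
    c(0.01, 0.50, 0.40, 0.10),  # August
    c(0.20, 0.67, 0.10, 0.02),  # October
    c(0.09, 0.49, 0.37, 0.04),  # November
    c(0.00, 1.00, 0.00, 0.00)   # January
  )
  tibble::tibble(
    label = rep(labels, each = 4),
    age = rep(0:3, times = 6),
    p = as.vector(t(P))
  )
}

#' Synthetic-data scenario
#'
#' Generating parameters for the simulator. The defaults are the canonical
#' northeast Florida scenario: seasonal growth with `L_inf = 448` mm,
#' `K = 0.47`, `C = 0.61`, `t_s = 0.21`, a summer birth pulse at
#' `t_b = 0.41`, per-age dispersions `(26.29, 27.48, 24.13, 40.30)` mm,
#' and the six study months with their sample sizes and age compositions.
#'
#' Recruitment is a point pulse by default (every fish born at `t_b`); an
#' optional normal jitter of individual birth dates (`birth_date_sd`, yr)
#' and an optional logistic size selectivity
#' (`selectivity = list(l50 = , slope = )`, mm) are available for
#' robustness experiments and are off by default.
#'
#' @param growth A [growth_params()] object.
#' @param sigmas Per-age-class standard deviations of length-at-age (mm).
#' @param months Months tibble (`label`, `sample_time`, `n`).
#' @param proportions Long proportions tibble (`label`, `age`, `p`).
#' @param birth_date_sd Standard deviation of individual birth dates (yr).
#' @param selectivity `NULL` or `list(l50, slope)` for logistic retention.
#' @return An object of class `lf_scenario`.
#' @examples
#' sc <- lf_scenario()
#' sum(sc$months$n)  # 2137 fish in the canonical scenario
#' @export
lf_scenario <- function(growth = growth_params(L_inf = 448, K = 0.47, t0 = 0,
                                               C = 0.61, t_s = 0.21, t_b = 0.41),
                        sigmas = c(26.29, 27.48, 24.13, 40.30),
                        months = study_months(),
                        proportions = study_proportions(),
                        birth_date_sd = 0,
                        selectivity = NULL) {
  stopifnot(inherits(growth, "growth_params"))
  if (any(sigmas <= 0)) rlang::abort("`sigmas` must be positive.")
  if (!is.null(selectivity))
    stopifnot(is.list(selectivity), all(c("l50", "slope") %in% names(selectivity)))
  structure(list(growth = growth, sigmas = sigmas, months = months,
                 proportions = proportions, birth_date_sd = birth_date_sd,
                 selectivity = selectivity),
            class = "lf_scenario")
}

#' @export
print.lf_scenario <- function(x, ...) {
  cat(sprintf("<lf_scenario> %d months, %d fish, %d age classes\n",
              nrow(x$months), sum(x$months$n), length(x$sigmas)))
  print(x$growth)
  invisible(x)
}

#' Simulate individual fish length records
#'
#' Draws, for every sampling month, `n` fish whose age class follows that
#' month's proportions-at-age and whose total length is normal around the
#' growth curve's mean length for that cohort's age, with the age class's
#' dispersion. Lengths below 1 mm are redrawn. The result has the same
#' schema as [read_length_records()] output, so synthetic and real data
#' are interchangeable downstream.
#'
#' @param scenario An [lf_scenario()].
#' @param seed Optional integer seed; a fixed seed gives byte-identical
#'   records.
#' @return Tibble with columns `fish_id`, `date` (ISO `yyyy-mm-dd`),
#'   `label`, `year_fraction`, `age_class`, `tl_mm`.
#' @examples
#' recs <- simulate_length_records(lf_scenario(), seed = 1)
#' nrow(recs)  # 2137
#' @export
simulate_length_records <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "lf_scenario"))
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_length_records(scenario)))

  gp <- scenario$growth
  n_ages <- length(scenario$sigmas)
  P <- proportions_matrix(scenario$proportions, scenario$months$label, n_ages)
  cs <- colSums(P)
  P <- sweep(P, 2, ifelse(cs > 0, cs, 1), "/")

  sim_month <- function(j) {
    m <- scenario$months[j, ]
    if (m$n <= 0) return(NULL)
    draw <- function(k) {
      ages_cl <- sample.int(n_ages, k, replace = TRUE, prob = P[, j]) - 1L
      tb_i <- gp$t_b
      if (scenario$birth_date_sd > 0)
        tb_i <- gp$t_b + stats::rnorm(k, 0, scenario$birth_date_sd)
      age <- (m$sample_time - tb_i) %% 1 + ages_cl
      mu <- vbgf_length(gp, age, seasonal = gp$C > 0)
      tl <- stats::rnorm(k, mu, scenario$sigmas[ages_cl + 1L])
      bad <- tl < 1
      while (any(bad)) {
        tl[bad] <- stats::rnorm(sum(bad), mu[bad], scenario$sigmas[ages_cl[bad] + 1L])
        bad <- tl < 1
      }
      tibble::tibble(age_class = ages_cl, tl_mm = tl)
    }
    if (is.null(scenario$selectivity)) {
      fish <- draw(m$n)
    } else {
      # rejection-sample until n fish are retained by the logistic curve
      sel <- scenario$selectivity
      keep <- list(); got <- 0L
      while (got < m$n) {
        cand <- draw(max(m$n, 100L))
        pr <- 1 / (1 + exp(-(cand$tl_mm - sel$l50) / sel$slope))
        cand <- cand[stats::runif(nrow(cand)) < pr, ]
        keep[[length(keep) + 1L]] <- cand
        got <- got + nrow(cand)
      }
      fish <- dplyr::bind_rows(keep)[seq_len(m$n), ]
    }
    cd <- calendar_date(m$sample_time)
    yr <- if ("year" %in% names(m)) m$year else 2014L
    dplyr::mutate(fish,
                  label = m$label,
                  date = sprintf("%d-%02d-%02d", yr, cd$month, cd$day),
                  year_fraction = m$sample_time)
  }
  out <- purrr::map_dfr(seq_len(nrow(scenario$months)), sim_month)
  out$fish_id <- sprintf("F%05d", seq_len(nrow(out)))
  dplyr::select(out, "fish_id", "date", "label", "year_fraction",
                "age_class", "tl_mm")
}
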