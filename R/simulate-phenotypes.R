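# Synthetic multi-center phenotype studies.
#
# The generator emulates the structure of a standardized multi-center
# sub-strain comparison: two strains (B6N, B6J), both sexes, several centers,
# and a mix of numeric, categorical and time-course parameters. Strain effects
# are standardized mean shifts (numeric/time-course) or per-strain prevalences
# (categorical); centers differ by an additive offset. Noise is Gaussian and
# categorical outcomes are Bernoulli -- the simplest structure satisfying the
# downstream tests' assumptions.

# Runs code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Define one simulated phenotype parameter
#'
#' @param name Parameter name.
#' @param kind One of `"numeric"`, `"categorical"`, `"timecourse"`.
#' @param d Standardized strain effect (mean shift in units of `noise_sd`,
#'   B6N minus B6J) for numeric and time-course parameters.
#' @param prevalence_n,prevalence_j Per-strain prevalence of the affected
#'   level for categorical parameters; scalars, or vectors with one entry per
#'   center (`NA` marks a center that did not measure the parameter).
#' @param baseline Grand mean for numeric/time-course parameters.
#' @param noise_sd Residual standard deviation (must be positive).
#' @param center_offsets Additive center offsets; scalar or one per center.
#' @param n_timepoints Number of time points for time-course parameters.
#' @return A `substrain_parameter` list.
#' @export
phenotype_parameter <- function(name,
                                kind = c("numeric", "categorical", "timecourse"),
                                d = 0,
                                prevalence_n = NULL, prevalence_j = NULL,
                                baseline = 0, noise_sd = 1,
                                center_offsets = 0, n_timepoints = 5L) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(prevalence_n) || is.null(prevalence_j)) {
      stop("categorical parameters need prevalence_n and prevalence_j", call. = FALSE)
    }
    pv <- c(prevalence_n, prevalence_j)
    if (any(pv < 0 | pv > 1, na.rm = TRUE)) {
      stop("prevalences must lie in [0, 1]", call. = FALSE)
    }
  } else if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive", call. = FALSE)
  }
  structure(list(name = name, kind = kind, d = d,
                 prevalence_n = prevalence_n, prevalence_j = prevalence_j,
                 baseline = baseline, noise_sd = noise_sd,
                 center_offsets = center_offsets,
                 n_timepoints = as.integer(n_timepoints)),
            class = "substrain_parameter")
}

#' Configure a simulated multi-center phenotype study
#'
#' @param parameters List of [phenotype_parameter()] definitions.
#' @param centers Character vector of center names.
#' @param n_per_group Animals per center x sex x strain group (scalar).
#' @param seed Integer seed; the same seed yields a bit-identical table.
#' @return A `substrain_study_config` list.
#' @export
study_config <- function(parameters, centers = c("HMGU", "ICS", "MRC", "WTSI"),
                         n_per_group = 20L, seed = 1L) {
  if (!length(parameters)) stop("at least one parameter required", call. = FALSE)
  if (n_per_group < 1) stop("group sizes must be >= 1", call. = FALSE)
  for (p in parameters) {
    if (!inherits(p, "substrain_parameter")) {
      stop("parameters must be built with phenotype_parameter()", call. = FALSE)
    }
    for (field in c("center_offsets", "prevalence_n", "prevalence_j")) {
      v <- p[[field]]
      if (!is.null(v) && !length(v) %in% c(1L, length(centers))) {
        stop("parameter '", p$name, "': ", field,
             " must be a scalar or one value per center", call. = FALSE)
      }
    }
  }
  structure(list(parameters = parameters, centers = centers,
                 n_per_group = as.integer(n_per_group), seed = as.integer(seed)),
            class = "substrain_study_config")
}

#' The default study configuration
#'
#' Parameter set used by the worked examples and the analysis scripts. The
#' settings are parameterized from published per-parameter summaries of the
#' C57BL/6N vs C57BL/6J comparison: visual acuity means of 0.314 (N) vs 0.399
#' (J) cycles/degree, mean retinal vein counts of 4.8 (N) vs 5.3 (J), fundus
#' flecking prevalences of 69.2%/44.6%/23.0% in N across three centers versus
#' 0% in J, plus a glucose-tolerance time course and a null control parameter.
#' Group sizes default to 20 per center/sex/strain, in the range of the
#' published per-center cohorts.
#'
#' @param n_per_group Animals per group; default 20.
#' @param seed Integer seed.
#' @return A `substrain_study_config`.
#' @export
default_study_config <- function(n_per_group = 20L, seed = 1L) {
  study_config(
    parameters = list(
      phenotype_parameter("visual_acuity", "numeric",
                          baseline = 0.399, noise_sd = 0.03,
                          d = (0.314 - 0.399) / 0.03),
      phenotype_parameter("retinal_veins", "numeric",
                          baseline = 5.3, noise_sd = 0.8,
                          d = (4.8 - 5.3) / 0.8),
      phenotype_parameter("fundus_flecking", "categorical",
                          prevalence_n = c(0.692, 0.446, 0.230, NA),
                          prevalence_j = c(0, 0, 0, NA)),
      phenotype_parameter("ipgtt_glucose", "timecourse",
                          baseline = 10, noise_sd = 1.5, d = -0.8,
                          n_timepoints = 5L,
                          center_offsets = c(0, 0.5, -0.5, 0.2)),
      phenotype_parameter("null_control", "numeric", d = 0)
    ),
    n_per_group = n_per_group, seed = seed
  )
}

#' Simulate a multi-center phenotype study
#'
#' Draws one measurement table from a [study_config()]: one row per animal per
#' parameter, with time courses emitted as comma-joined ordered series in the
#' `value` column. Numeric values are Gaussian around
#' `baseline + center_offset` with the B6N group shifted by `d * noise_sd`;
#' categorical outcomes are Bernoulli draws of `"affected"` at the configured
#' per-strain prevalence. A center whose prevalence is `NA` contributes no
#' rows for that parameter (absent data). Output is deterministic under the
#' config seed.
#'
#' @param config A `substrain_study_config`.
#' @return A tibble with columns `center`, `parameter`, `kind`, `sex`,
#'   `strain`, `animal_id`, `group_key`, `value` (character; comma-joined for
#'   time courses).
#' @export
#' @examples
#' tab <- generate_phenotype_study(default_study_config(n_per_group = 5))
#' head(tab)
generate_phenotype_study <- function(config) {
  stopifnot(inherits(config, "substrain_study_config"))
  centers <- config$centers
  n <- config$n_per_group
  with_seed(config$seed, {
    out <- list()
    for (p in config$parameters) {
      offsets <- rep_len(p$center_offsets %||% 0, length(centers))
      for (ci in seq_along(centers)) {
        for (sex in c("male", "female")) {
          for (strain in c("B6N", "B6J")) {
            if (p$kind == "categorical") {
              prev <- if (strain == "B6N") p$prevalence_n else p$prevalence_j
              prev <- rep_len(prev, length(centers))[ci]
              if (is.na(prev)) next
              vals <- ifelse(stats::runif(n) < prev, "affected", "unaffected")
            } else {
              mu <- p$baseline + offsets[ci] +
                if (strain == "B6N") p$d * p$noise_sd else 0
              if (p$kind == "timecourse") {
                m <- matrix(stats::rnorm(n * p$n_timepoints, mu, p$noise_sd),
                            nrow = n)
                vals <- apply(m, 1, function(v)
                  paste(sprintf("%.10g", v), collapse = ","))
              } else {
                vals <- sprintf("%.10g", stats::rnorm(n, mu, p$noise_sd))
              }
            }
            out[[length(out) + 1L]] <- tibble(
              center = centers[ci], parameter = p$name, kind = p$kind,
              sex = sex, strain = strain,
              animal_id = sprintf("%s_%s_%s_%03d", centers[ci], sex, strain,
                                  seq_len(n)),
              group_key = "g1", value = vals
            )
          }
        }
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Write / read a phenotype measurement table
#'
#' Plain TSV with a one-line header; `value` holds scalars or comma-joined
#' time-course series.
#'
#' @param x Phenotype table as returned by [generate_phenotype_study()].
#' @param path File path.
#' @return `read_phenotype_table()` returns the tibble; `write_phenotype_table()`
#'   returns `path` invisibly.
#' @export
write_phenotype_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character"))
}
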