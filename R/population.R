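#' Simulate a synthetic population of families
#'
#' Draws a population with the statistical structure the analytic model
#' assumes. Each family is independently schizotypal with probability
#' `prop_schizotypal`; schizotypal families are low-fitness with probability
#' `p_low` and high-fitness otherwise; non-schizotypal families have no
#' fitness class. Each member of a high-fitness schizotypal family is
#' diagnosed independently with probability `p_diag_high`, of a low-fitness
#' family with `r * p_diag_high`, and of a non-schizotypal family with
#' `p_diag_nonschizotypal`. Offspring counts are Poisson with mean
#' `base_mean_offspring` times the class relative fertility (`w_high`,
#' `w_low`, or 1 for non-schizotypal families). Diagnosis and fertility are
#' drawn independently within class: all fertility effects are routed
#' through class membership, since the fertility difference `d` already
#' includes the fertility-reducing effects of schizophrenia.
#'
#' The same `simulation_params` (including the seed) reproduce the identical
#' population.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `population`: a list with `params` and
#'   `families`, a data frame with one row per family and columns
#'   `family_id`, `schizotypal` (logical), `fitness_class`
#'   (`"high"`, `"low"` or `"not_applicable"`), `n_members`, `n_diagnosed`,
#'   and `offspring` (list column of per-member non-negative integer
#'   counts).
#' @examples
#' pop <- simulate_population(
#'   simulation_params(ssm_params(r = 3, d = 1), n_families = 100, seed = 42))
#' table(pop$families$fitness_class)
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_families
  fs <- params$family_size
  ssm <- params$ssm

  schizotypal <- stats::runif(n) < params$prop_schizotypal
  fitness_class <- rep("not_applicable", n)
  n_schiz <- sum(schizotypal)
  if (n_schiz > 0L) {
    fitness_class[schizotypal] <-
      ifelse(stats::runif(n_schiz) < ssm$p_low, "low", "high")
  }

  p_diag <- rep(params$p_diag_nonschizotypal, n)
  p_diag[fitness_class == "high"] <- params$p_diag_high
  p_diag[fitness_class == "low"] <- ssm$r * params$p_diag_high
  n_diagnosed <- stats::rbinom(n, size = fs, prob = p_diag)

  w_class <- rep(1, n)
  w_class[fitness_class == "high"] <- ssm$w_high
  w_class[fitness_class == "low"] <- ssm$w_low
  counts <- stats::rpois(n * fs, lambda = rep(params$base_mean_offspring * w_class,
                                              each = fs))
  offspring <- split(as.integer(counts),
                     rep(seq_len(n), each = fs))
  names(offspring) <- NULL

  families <- data.frame(
    family_id = seq_len(n),
    schizotypal = schizotypal,
    fitness_class = fitness_class,
    n_members = rep(fs, n),
    n_diagnosed = n_diagnosed,
    stringsAsFactors = FALSE
  )
  families$offspring <- offspring
  new_population(params, families)
}

new_population <- function(params, families) {
  structure(list(params = params, families = families), class = "population")
}

#' @export
print.population <- function(x, ...) {
  f <- x$families
  cat(sprintf("Simulated family population: %d families x %d members (seed %d)\n",
              nrow(f), x$params$family_size, x$params$seed))
  cat(sprintf("  schizotypal: %d (%d low-fitness, %d high-fitness)\n",
              sum(f$schizotypal), sum(f$fitness_class == "low"),
              sum(f$fitness_class == "high")))
  cat(sprintf("  diagnosed individuals: %d\n", sum(f$n_diagnosed)))
  invisible(x)
}

# Per-family offspring totals and member counts, used by the estimators.
family_totals <- function(pop) {
  f <- pop$families
  data.frame(
    family_id = f$family_id,
    schizotypal = f$schizotypal,
    fitness_class = f$fitness_class,
    n_members = f$n_members,
    n_diagnosed = f$n_diagnosed,
    offspring_total = vapply(f$offspring, sum, numeric(1))
  )
}

#' Write a simulated population to delimited text
#'
#' Serialises a population to a tab-separated table (one row per family,
#' offspring counts encoded as a comma-delimited list) plus a JSON sidecar
#' `<path>.params.json` holding the simulation parameters, so the round trip
#' through [read_population()] is lossless.
#'
#' @param pop A `population` object.
#' @param path Path of the TSV file to write; the params sidecar is written
#'   next to it.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  f <- pop$families
  out <- data.frame(
    family_id = f$family_id,
    schizotypal = f$schizotypal,
    fitness_class = f$fitness_class,
    n_members = f$n_members,
    n_diagnosed = f$n_diagnosed,
    offspring_counts = vapply(f$offspring, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- pop$params
  meta <- list(
    r = p$ssm$r, d = p$ssm$d, W = p$ssm$W, p_low = p$ssm$p_low,
    n_families = p$n_families, prop_schizotypal = p$prop_schizotypal,
    family_size = p$family_size, p_diag_high = p$p_diag_high,
    p_diag_nonschizotypal = p$p_diag_nonschizotypal,
    base_mean_offspring = p$base_mean_offspring, seed = p$seed
  )
  jsonlite::write_json(meta, paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a population written by [write_population()]
#'
#' Parses the TSV table and the JSON params sidecar back into a
#' `population` object, validating every row; a malformed row (negative
#' offspring count, diagnosed count out of range, member-count mismatch)
#' raises an error naming the offending row.
#'
#' @param path Path of the TSV file written by [write_population()].
#' @return A `population` object equal to the one written.
#' @export
read_population <- function(path) {
  if (!file.exists(path))
    stop("population file not found: ", path, call. = FALSE)
  sidecar <- paste0(path, ".params.json")
  if (!file.exists(sidecar))
    stop("params sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  params <- simulation_params(
    ssm = ssm_params(r = meta$r, d = meta$d, W = meta$W, p_low = meta$p_low),
    n_families = meta$n_families,
    prop_schizotypal = meta$prop_schizotypal,
    family_size = meta$family_size,
    p_diag_high = meta$p_diag_high,
    p_diag_nonschizotypal = meta$p_diag_nonschizotypal,
    base_mean_offspring = meta$base_mean_offspring,
    seed = meta$seed
  )
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "logical", "character",
                                          "integer", "integer", "character"),
                           stringsAsFactors = FALSE)
  offspring <- lapply(strsplit(tab$offspring_counts, ",", fixed = TRUE),
                      function(x) as.integer(x))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    counts <- offspring[[i]]
    if (anyNA(counts) || any(counts < 0))
      stop("row ", i, " (family ", row$family_id,
           "): offspring counts must be non-negative integers", call. = FALSE)
    if (length(counts) != row$n_members)
      stop("row ", i, " (family ", row$family_id, "): ", length(counts),
           " offspring counts for ", row$n_members, " members", call. = FALSE)
    if (is.na(row$n_diagnosed) || row$n_diagnosed < 0 ||
        row$n_diagnosed > row$n_members)
      stop("row ", i, " (family ", row$family_id,
           "): diagnosed count out of [0, n_members]", call. = FALSE)
    if (!row$fitness_class %in% c("high", "low", "not_applicable"))
      stop("row ", i, " (family ", row$family_id,
           "): unknown fitness class '", row$fitness_class, "'", call. = FALSE)
    if (xor(row$schizotypal, row$fitness_class != "not_applicable"))
      stop("row ", i, " (family ", row$family_id,
           "): fitness class inconsistent with schizotypal flag", call. = FALSE)
  }
  families <- data.frame(
    family_id = tab$family_id,
    schizotypal = tab$schizotypal,
    fitness_class = tab$fitness_class,
    n_members = tab$n_members,
    n_diagnosed = tab$n_diagnosed,
    stringsAsFactors = FALSE
  )
  families$offspring <- offspring
  new_population(params, families)
}
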