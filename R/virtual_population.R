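#' @name virtual_population
#' @title Virtual patient populations
#' @description
#' A virtual subject carries eight descriptors. Six X variables govern the
#' patient-treatment interaction along the drug's causal chain:
#' `x_absorption` (subject-specific oral absorption factor), `x_age`
#' (years; scales drug elimination), `x_emax_genes` (gene-expression summary
#' setting the maximal receptor stimulus), `x_binding_genes` (modulation of
#' drug-target binding affinity), `x_transduction` (composite
#' allele/ionic-strength/transducer availability modulating signal
#' transduction) and `x_sympathetic` (sympathetic drive setting the strength
#' of the homeostatic feedback). Two Y variables are specific to the
#' disease: `y_biomarker` (the key biological variable of the disease
#' mechanism, whose link to the event risk is altered by the drug) and
#' `y_risk_factor` (a risk factor the drug does not touch).
#' Descriptor distributions are Normal or log-Normal, optionally truncated.
NULL

DESCRIPTOR_NAMES <- c("x_absorption", "x_age", "x_emax_genes",
                      "x_binding_genes", "x_transduction", "x_sympathetic",
                      "y_biomarker", "y_risk_factor")

DESCRIPTOR_CATEGORY <- c(x_absorption = "X", x_age = "X", x_emax_genes = "X",
                         x_binding_genes = "X", x_transduction = "X",
                         x_sympathetic = "X", y_biomarker = "Y",
                         y_risk_factor = "Y")

# Descriptors entering the chain multiplicatively must be positive.
MULTIPLICATIVE_DESCRIPTORS <- c("x_absorption", "x_emax_genes",
                                "x_binding_genes", "x_transduction")

#' Specify one patient-descriptor distribution
#'
#' @param name One of the eight descriptor names (see
#'   [virtual_population]).
#' @param distribution `"normal"` or `"lognormal"`. A log-Normal is
#'   parameterized by the location and scale of the underlying normal on the
#'   log scale.
#' @param location,scale Distribution parameters; `scale > 0`.
#' @param bounds Optional length-2 `c(low, high)` truncation interval,
#'   enforced by rejection sampling.
#' @return A list of class `"descriptor_spec"`.
#' @export
descriptor_spec <- function(name, distribution = c("normal", "lognormal"),
                            location = 0, scale = 1, bounds = NULL) {
  distribution <- match.arg(distribution)
  structure(list(name = name,
                 category = unname(DESCRIPTOR_CATEGORY[name]),
                 distribution = distribution,
                 location = location, scale = scale, bounds = bounds),
            class = "descriptor_spec")
}

#' Specify a virtual population
#'
#' @param descriptors A list of eight [descriptor_spec()] objects covering
#'   each descriptor name exactly once.
#' @param size Number of subjects to sample.
#' @param seed Integer RNG seed; the same spec and seed always reproduce the
#'   same population bit for bit.
#' @return A list of class `"population_spec"`.
#' @seealso [default_population_spec()], [sample_population()],
#'   [validate_population_spec()]
#' @export
population_spec <- function(descriptors, size = 200, seed = 1) {
  spec <- structure(list(descriptors = descriptors, size = size, seed = seed),
                    class = "population_spec")
  findings <- validate_population_spec(spec)
  if (length(findings) > 0L) {
    stop_user("invalid population spec:\n  ",
              paste(findings, collapse = "\n  "))
  }
  spec
}

#' Default virtual-population specification
#'
#' A plausible sham-case population for a cardiovascular one-year-risk
#' setting: multiplicative X descriptors are log-Normal centred at 1 with
#' moderate biological spread, age is Normal(60, 10) truncated to 30-90
#' years, sympathetic drive is log-Normal, and the two Y disease descriptors
#' are standard-normal scores feeding the logistic risk model. These are
#' illustrative defaults for a synthetic cohort, not estimates from any real
#' population.
#'
#' @param size Number of subjects (default 200, the size used for the
#'   reference effect-model scatter).
#' @param seed RNG seed.
#' @return A `"population_spec"`.
#' @export
default_population_spec <- function(size = 200, seed = 1) {
  population_spec(list(
    descriptor_spec("x_absorption", "lognormal", 0, 0.25),
    descriptor_spec("x_age", "normal", 60, 10, bounds = c(30, 90)),
    descriptor_spec("x_emax_genes", "lognormal", 0, 0.30),
    descriptor_spec("x_binding_genes", "lognormal", 0, 0.30),
    descriptor_spec("x_transduction", "lognormal", 0, 0.30),
    descriptor_spec("x_sympathetic", "lognormal", 0, 0.40),
    descriptor_spec("y_biomarker", "normal", 0, 1),
    descriptor_spec("y_risk_factor", "normal", 0, 1)
  ), size = size, seed = seed)
}

#' Validate a population specification
#'
#' Returns findings instead of raising, so configuration files can be
#' checked and all problems reported at once.
#'
#' @param spec A `"population_spec"` (or a bare list shaped like one).
#' @return A character vector of findings; empty iff the spec is valid.
#' @export
validate_population_spec <- function(spec) {
  findings <- character(0)
  note <- function(...) findings <<- c(findings, paste0(...))
  if (!is.list(spec$descriptors)) {
    return("descriptors must be a list of descriptor_spec objects")
  }
  names_seen <- vapply(spec$descriptors, function(d) d$name %||% "",
                       character(1))
  unknown <- setdiff(names_seen, DESCRIPTOR_NAMES)
  for (u in unknown) note("unknown descriptor name: ", u)
  missing <- setdiff(DESCRIPTOR_NAMES, names_seen)
  for (m in missing) note("missing descriptor: ", m)
  dup <- unique(names_seen[duplicated(names_seen)])
  for (d in dup) note("duplicated descriptor: ", d)
  for (d in spec$descriptors) {
    if (!is.null(d$name) && !d$name %in% DESCRIPTOR_NAMES) next
    lab <- d$name %||% "<unnamed>"
    if (!is_num1(d$scale) || d$scale <= 0) {
      note(lab, ": scale must be > 0")
    }
    if (!is_num1(d$location)) note(lab, ": location must be a finite number")
    if (!is.null(d$distribution) &&
        !d$distribution %in% c("normal", "lognormal")) {
      note(lab, ": distribution must be normal or lognormal")
    }
    if (!is.null(d$bounds)) {
      if (length(d$bounds) != 2L || !all(is.finite(d$bounds)) ||
          d$bounds[1L] >= d$bounds[2L]) {
        note(lab, ": bounds must satisfy low < high")
      }
    }
  }
  if (!is_count(spec$size) || spec$size < 1) note("size must be >= 1")
  if (!is_count(spec$seed)) note("seed must be an integer")
  findings
}

# Draw n values from one descriptor, honouring truncation by rejection
# sampling (cap of 1000 resampling rounds per descriptor).
sample_descriptor <- function(d, n) {
  draw <- function(k) {
    switch(d$distribution,
           normal = stats::rnorm(k, d$location, d$scale),
           lognormal = stats::rlnorm(k, d$location, d$scale))
  }
  x <- draw(n)
  if (!is.null(d$bounds)) {
    lo <- d$bounds[1L]; hi <- d$bounds[2L]
    for (attempt in seq_len(1000L)) {
      bad <- which(x < lo | x > hi)
      if (length(bad) == 0L) break
      x[bad] <- draw(length(bad))
    }
    if (any(x < lo | x > hi)) {
      stop_user("descriptor ", d$name,
                ": truncation bounds leave too little probability mass")
    }
  }
  x
}

#' Sample a virtual population
#'
#' Draws `spec$size` subjects with independent descriptor values from the
#' configured distributions. Sampling is fully determined by `spec$seed`;
#' the caller's RNG state is left untouched.
#'
#' @param spec A `"population_spec"`, e.g. [default_population_spec()].
#' @return A `data.frame` of class `c("virtual_population", "data.frame")`
#'   with `subject_id` and the eight descriptor columns; the seed is
#'   attached as `attr(, "seed")`.
#' @examples
#' pop <- sample_population(default_population_spec(size = 50, seed = 7))
#' nrow(pop)
#' @export
sample_population <- function(spec) {
  findings <- validate_population_spec(spec)
  if (length(findings) > 0L) {
    stop_user("invalid population spec:\n  ",
              paste(findings, collapse = "\n  "))
  }
  n <- spec$size
  descs <- spec$descriptors[order(match(
    vapply(spec$descriptors, `[[`, character(1), "name"), DESCRIPTOR_NAMES))]
  cols <- with_seed(spec$seed, {
    lapply(descs, sample_descriptor, n = n)
  })
  names(cols) <- DESCRIPTOR_NAMES
  pop <- data.frame(subject_id = seq_len(n), cols)
  attr(pop, "seed") <- spec$seed
  class(pop) <- c("virtual_population", "data.frame")
  pop
}

#' Write or read a virtual population as CSV
#'
#' The CSV has `subject_id` plus the eight descriptor columns and
#' round-trips losslessly to at least 12 significant digits. The reader also
#' accepts externally constructed populations (e.g. descriptor values taken
#' from a real cohort), provided all eight descriptor columns are present.
#'
#' @param population A `virtual_population` (or compatible `data.frame`).
#' @param path CSV path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns a `virtual_population`.
#' @export
write_population <- function(population, path) {
  need <- c("subject_id", DESCRIPTOR_NAMES)
  if (!all(need %in% names(population))) {
    stop_user("population must have columns: ", paste(need, collapse = ", "))
  }
  out <- population[need]
  for (col in DESCRIPTOR_NAMES) {
    out[[col]] <- format(out[[col]], digits = 15, scientific = TRUE,
                         trim = TRUE)
  }
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_user("cannot write to: ", path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop_user("population file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", DESCRIPTOR_NAMES)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_user("population file missing column(s): ",
              paste(missing, collapse = ", "))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1L]
      stop_user("malformed value in column ", col, ", row ", row)
    }
    df[[col]] <- v
  }
  df$subject_id <- as.integer(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop_user("subject_id values must be unique")
  bad <- vapply(MULTIPLICATIVE_DESCRIPTORS,
                function(col) any(df[[col]] <= 0), logical(1))
  if (any(bad)) {
    stop_user("descriptor ", MULTIPLICATIVE_DESCRIPTORS[bad][1L],
              " must be strictly positive")
  }
  df <- df[need]
  class(df) <- c("virtual_population", "data.frame")
  df
}
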