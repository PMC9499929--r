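#' @useDynLib bearcadian, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SEASON_CODES <- c("sp", "es", "ls", "fa")
SEASON_NAMES <- c(sp = "spring", es = "early summer", ls = "late summer",
                  fa = "fall")
SEX_CODES <- c("F", "M")

# Structural definition of the 13 candidate models. Each model combines
#   hour effect : "hour" (lambda_i), "hour_season" (lambda_ir),
#                 "hour_season_sex" (lambda_irs)
#   fixed       : "none", "additive" (mu_s + gamma_r),
#                 "interaction" (xi_rs), "season" (gamma_r)
#   anthro      : "none", "combined" (x1 all roads + x4 settlements),
#                 "split" (x2 primary + x3 secondary + x4 settlements)
#   by_season   : whether each anthropogenic block gets season-specific
#                 (beta_jr, phi_jr) or shared (beta_j, phi_j) coefficients
MODEL_TABLE <- list(
  list(id = 1L,  hour = "hour",            fixed = "none",        anthro = "none",     by_season = FALSE),
  list(id = 2L,  hour = "hour",            fixed = "additive",    anthro = "combined", by_season = FALSE),
  list(id = 3L,  hour = "hour",            fixed = "additive",    anthro = "split",    by_season = FALSE),
  list(id = 4L,  hour = "hour_season_sex", fixed = "additive",    anthro = "combined", by_season = TRUE),
  list(id = 5L,  hour = "hour_season_sex", fixed = "additive",    anthro = "split",    by_season = TRUE),
  list(id = 6L,  hour = "hour_season_sex", fixed = "interaction", anthro = "combined", by_season = FALSE),
  list(id = 7L,  hour = "hour_season_sex", fixed = "interaction", anthro = "split",    by_season = FALSE),
  list(id = 8L,  hour = "hour_season_sex", fixed = "interaction", anthro = "combined", by_season = TRUE),
  list(id = 9L,  hour = "hour_season_sex", fixed = "interaction", anthro = "split",    by_season = TRUE),
  list(id = 10L, hour = "hour_season",     fixed = "season",      anthro = "combined", by_season = FALSE),
  list(id = 11L, hour = "hour_season",     fixed = "season",      anthro = "split",    by_season = FALSE),
  list(id = 12L, hour = "hour_season",     fixed = "season",      anthro = "combined", by_season = TRUE),
  list(id = 13L, hour = "hour_season",     fixed = "season",      anthro = "split",    by_season = TRUE)
)

#' One of the thirteen candidate model structures
#'
#' Returns the structural specification of model `id` in the registry: which
#' hour-of-day effect it carries (`lambda_i`, `lambda_ir` or `lambda_irs`),
#' which fixed sex/season terms, and which anthropogenic distance block
#' (combined roads `x1` + settlements `x4`, or primary `x2` + secondary `x3`
#' + settlements `x4`), season-interacting or shared.
#'
#' @param id integer 1..13.
#' @return object of class `model_spec`.
#' @seealso [model_registry()]
#' @export
model_spec <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 13L) {
    stop("model id must be a single integer in 1..13")
  }
  m <- MODEL_TABLE[[id]]
  m$features <- switch(m$anthro, none = integer(0), combined = c(1L, 4L),
                       split = c(2L, 3L, 4L))
  structure(m, class = "model_spec")
}

#' Registry of all thirteen model structures
#'
#' @return list of [model_spec()] objects, ids 1..13.
#' @export
model_registry <- function() lapply(1:13, model_spec)

# Strata of the hour-of-day effect for a model: one 24-vector per stratum.
#   "hour"            -> one pooled stratum
#   "hour_season"     -> one per season (4)
#   "hour_season_sex" -> one per season x sex (8), sex-major order
lambda_strata <- function(spec) {
  switch(spec$hour,
    hour = data.frame(stratum = 1L, season = NA_integer_, sex = NA_integer_,
                      label = "all", stringsAsFactors = FALSE),
    hour_season = data.frame(stratum = 1:4, season = 1:4, sex = NA_integer_,
                             label = SEASON_CODES, stringsAsFactors = FALSE),
    hour_season_sex = {
      g <- expand.grid(season = 1:4, sex = 1:2)
      data.frame(stratum = 1:8, season = g$season, sex = g$sex,
                 label = paste0(SEASON_CODES[g$season], ".", SEX_CODES[g$sex]),
                 stringsAsFactors = FALSE)
    })
}

# Map observations to their lambda stratum index.
lambda_stratum_of <- function(spec, season, sex) {
  switch(spec$hour,
    hour = rep.int(1L, length(season)),
    hour_season = as.integer(season),
    hour_season_sex = as.integer((sex - 1L) * 4L + season))
}

# Free (non-reference) fixed-effect coefficients of a model. Reference
# categories: mu_F = 0, gamma_spring = 0, xi_{spring,F} = 0 (female in
# spring), matching corner constraints.
fixed_coef_names <- function(spec) {
  switch(spec$fixed,
    none = character(0),
    additive = c("mu_M", paste0("gamma_", SEASON_CODES[2:4])),
    season = paste0("gamma_", SEASON_CODES[2:4]),
    interaction = {
      g <- expand.grid(season = 1:4, sex = 1:2)
      g <- g[!(g$season == 1L & g$sex == 1L), ]
      paste0("xi_", SEASON_CODES[g$season], "_", SEX_CODES[g$sex])
    })
}

# n x F matrix of indices into the free fixed coefficients (0 = reference).
fixed_design <- function(spec, season, sex) {
  n <- length(season)
  switch(spec$fixed,
    none = matrix(integer(0), n, 0),
    additive = cbind(mu = ifelse(sex == 2L, 1L, 0L),
                     gamma = ifelse(season > 1L, season, 0L)),
    season = cbind(gamma = ifelse(season > 1L, season - 1L, 0L)),
    interaction = {
      idx <- (sex - 1L) * 4L + season   # 1..8, 1 = female spring (reference)
      cbind(xi = ifelse(idx == 1L, 0L, idx - 1L))
    })
}

# Names of the anthropogenic coefficient groups, in sampler order
# (feature-major, season within feature when by_season).
anthro_coef_names <- function(spec, prefix) {
  if (spec$anthro == "none") return(character(0))
  unlist(lapply(spec$features, function(j) {
    if (spec$by_season) paste0(prefix, "_x", j, "_", SEASON_CODES)
    else paste0(prefix, "_x", j)
  }))
}

#' Render a model's formula
#'
#' Human-readable linear-predictor formula for logging and the selection
#' table, in the field's notation (subscripts i = hour, r = season, s = sex,
#' k = individual).
#'
#' @param spec a [model_spec()].
#' @return single character string.
#' @export
render_formula <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- switch(spec$hour, hour = "lambda_i", hour_season = "lambda_ir",
                  hour_season_sex = "lambda_irs")
  terms <- c(terms, "omega_k")
  terms <- c(terms, switch(spec$fixed, none = NULL,
                           additive = c("mu_s", "gamma_r"),
                           season = "gamma_r", interaction = "xi_rs"))
  if (spec$anthro != "none") {
    sfx <- if (spec$by_season) "r" else ""
    terms <- c(terms, sprintf("beta_%d%s*exp(-phi_%d%s*x%d)",
                              spec$features, sfx, spec$features, sfx,
                              spec$features))
  }
  paste(terms, collapse = " + ")
}

# Number of season-interacting terms (the K column of the selection table):
# a season-indexed hour effect, the sex:season interaction, and each
# season-indexed anthropogenic block each count one.
interaction_count <- function(spec) {
  k <- 0L
  if (spec$hour %in% c("hour_season", "hour_season_sex")) k <- k + 1L
  if (spec$fixed == "interaction") k <- k + 1L
  if (spec$by_season) k <- k + length(spec$features)
  k
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model %d: y = %s + eps\n", x$id, render_formula(x)))
  invisible(x)
}

#' Serialize / restore the model registry
#'
#' The registry round-trips through a plain JSON list (one object per model
#' with its structural fields and rendered formula).
#'
#' @param path file path to write to / read from.
#' @return `registry_to_json` returns `path` invisibly; `registry_from_json`
#'   returns a list of `model_spec` objects.
#' @export
registry_to_json <- function(path) {
  reg <- lapply(model_registry(), function(m) {
    list(id = m$id, hour = m$hour, fixed = m$fixed, anthro = m$anthro,
         by_season = m$by_season, K = interaction_count(m),
         formula = render_formula(m))
  })
  jsonlite::write_json(reg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(m) model_spec(m$id))
}
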