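#' Specification of one adherence-index component
#'
#' Each of the 16 diet components contributes 0-10 points to the 0-160
#' index through a continuous piecewise-linear score:
#' \describe{
#'   \item{adequacy}{higher intake is better; 0 points at or below
#'     `zero_score_cutoff`, 10 at or above `full_score_cutoff`, linear in
#'     between.}
#'   \item{limit}{lower intake is better; 10 points at or below
#'     `full_score_cutoff`, 0 at or above `zero_score_cutoff`.}
#'   \item{range}{a target band; `full_score_cutoff` is the length-2 band
#'     earning 10 points, `zero_score_cutoff` the length-2 outer interval at
#'     (or beyond) which the score is 0, with linear ramps between.}
#' }
#'
#' @param name Component label.
#' @param kind One of `"adequacy"`, `"limit"`, `"range"`.
#' @param full_score_cutoff Intake earning 10 points (length 2 for
#'   `"range"`).
#' @param zero_score_cutoff Intake earning 0 points (length 2 for
#'   `"range"`).
#' @param cap_rule `NULL`, or a list `list(percentile = p, target = "full"
#'   or "zero")` marking a cutoff to be replaced by the per-country `p`-th
#'   percentile of observed intake (see [derive_caps()]). The default target
#'   is `"full"` for adequacy components and `"zero"` for limit components.
#' @return An object of class `"component_spec"`.
#' @export
component_spec <- function(name, kind = c("adequacy", "limit", "range"),
                           full_score_cutoff, zero_score_cutoff,
                           cap_rule = NULL) {
  kind <- match.arg(kind)
  f <- as.numeric(full_score_cutoff)
  z <- as.numeric(zero_score_cutoff)
  if (any(!is.finite(c(f, z))) || any(c(f, z) < 0))
    stop("cutoffs must be finite and non-negative", call. = FALSE)
  if (kind == "range") {
    if (length(f) != 2L || length(z) != 2L)
      stop("'range' components need length-2 cutoffs", call. = FALSE)
    if (!(z[1] <= f[1] && f[1] <= f[2] && f[2] <= z[2]))
      stop("'range' cutoffs must be nested: zero[1] <= full[1] <= full[2] ",
           "<= zero[2]", call. = FALSE)
  } else {
    if (length(f) != 1L || length(z) != 1L)
      stop("'", kind, "' components need scalar cutoffs", call. = FALSE)
    if (kind == "adequacy" && !(z < f))
      stop("adequacy components require zero_score_cutoff < ",
           "full_score_cutoff", call. = FALSE)
    if (kind == "limit" && !(f < z))
      stop("limit components require full_score_cutoff < ",
           "zero_score_cutoff", call. = FALSE)
  }
  if (!is.null(cap_rule)) {
    if (!is.list(cap_rule) || is.null(cap_rule$percentile))
      stop("'cap_rule' must be NULL or list(percentile =, target =)",
           call. = FALSE)
    p <- cap_rule$percentile
    if (!is.finite(p) || p < 0 || p > 100)
      stop("cap percentile must lie in [0, 100]", call. = FALSE)
    if (is.null(cap_rule$target))
      cap_rule$target <- if (kind == "limit") "zero" else "full"
    if (!cap_rule$target %in% c("full", "zero"))
      stop("cap target must be 'full' or 'zero'", call. = FALSE)
  }
  structure(list(name = name, kind = kind, full_score_cutoff = f,
                 zero_score_cutoff = z, cap_rule = cap_rule),
            class = "component_spec")
}

#' Score one diet component
#'
#' Piecewise-linear interpolation between the zero-score and full-score
#' cutoffs, clamped to `[0, 10]`. Adequacy components are non-decreasing in
#' intake, limit components non-increasing, and range components score 10
#' inside the target band with linear ramps to 0 outside it.
#'
#' @param intake Non-negative intake amount(s), in the component's units.
#' @param spec A [component_spec()].
#' @return Score(s) in `[0, 10]`.
#' @examples
#' sp <- component_spec("fruits", "adequacy", full_score_cutoff = 200,
#'                      zero_score_cutoff = 0)
#' score_component(c(0, 100, 200, 400), sp)  # 0, 5, 10, 10
#' @export
score_component <- function(intake, spec) {
  if (!inherits(spec, "component_spec"))
    stop("'spec' must be a component_spec object", call. = FALSE)
  if (any(!is.finite(intake)) || any(intake < 0))
    stop("intake must be finite and non-negative", call. = FALSE)
  f <- spec$full_score_cutoff
  z <- spec$zero_score_cutoff
  knots <- switch(spec$kind,
    adequacy = list(x = c(z, f), y = c(0, 10)),
    limit    = list(x = c(f, z), y = c(10, 0)),
    range    = list(x = c(z[1], f[1], f[2], z[2]), y = c(0, 10, 10, 0)))
  ## collapse coincident knots (e.g. a band touching its outer interval)
  keep <- !duplicated(knots$x)
  x <- knots$x[keep]; y <- knots$y[keep]
  out <- stats::approx(x, y, xout = intake, rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), 10)
}

#' Sum component scores into the adherence index
#'
#' The index is the plain sum of the 16 component scores, ranging 0-160.
#'
#' @param component_scores Numeric vector of exactly 16 scores in
#'   `[0, 10]`, or a matrix/data frame with 16 columns (one row per
#'   subject).
#' @return Index value(s) in `[0, 160]`.
#' @export
compute_index <- function(component_scores) {
  if (is.data.frame(component_scores))
    component_scores <- as.matrix(component_scores)
  if (is.matrix(component_scores)) {
    if (ncol(component_scores) != 16L)
      stop("expected 16 component scores, got ", ncol(component_scores),
           call. = FALSE)
    scores <- component_scores
  } else {
    if (length(component_scores) != 16L)
      stop("expected 16 component scores, got ", length(component_scores),
           call. = FALSE)
    scores <- matrix(component_scores, nrow = 1L)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 10))
    stop("component scores must lie in [0, 10]", call. = FALSE)
  out <- rowSums(scores)
  if (length(out) == 1L && !is.matrix(component_scores)) out[[1]] else out
}

#' Replace percentile-capped cutoffs by per-country empirical percentiles
#'
#' Components whose `cap_rule` names a percentile (e.g. the 85th for
#' sodium and sweets, the 100th for whole grains and low-fat meat) have the
#' targeted cutoff replaced by that percentile of the observed intake
#' distribution, computed separately within each country
#' (linear-interpolation empirical quantile, [stats::quantile()] type 7).
#'
#' @param intakes Data frame with a `country` column and one column per
#'   component (named as in `specs`).
#' @param specs List of [component_spec()] objects.
#' @return A named list, one element per country, each a list of updated
#'   specs. Components without a cap rule are returned unchanged.
#' @export
derive_caps <- function(intakes, specs) {
  if (!"country" %in% names(intakes))
    stop("'intakes' must have a 'country' column", call. = FALSE)
  countries <- if (is.factor(intakes$country)) levels(intakes$country)
               else unique(intakes$country)
  out <- lapply(countries, function(cty) {
    sub <- intakes[intakes$country == cty, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no intake records for country stratum '", cty, "'",
           call. = FALSE)
    lapply(specs, function(sp) {
      if (is.null(sp$cap_rule)) return(sp)
      if (!sp$name %in% names(sub))
        stop("no intake column for component '", sp$name, "'",
             call. = FALSE)
      q <- unname(stats::quantile(sub[[sp$name]],
                                  sp$cap_rule$percentile / 100,
                                  type = 7, na.rm = TRUE))
      if (sp$cap_rule$target == "full") sp$full_score_cutoff <- q
      else sp$zero_score_cutoff <- q
      sp
    })
  })
  names(out) <- countries
  out
}

#' Apply the study's record-level exclusion filters
#'
#' Drops intake records that are incomplete, lack supplement-use data, or
#' report implausible energy intake. Rules are applied in a fixed order and
#' each excluded record is tagged with its first matching reason:
#' `incomplete_diet`, `missing_supplement_data`, `low_energy` (< 500
#' kcal/day), `high_energy` (> 3500 kcal/day). Energy of exactly 500 or
#' 3500 kcal is kept (the bounds are strict).
#'
#' @param records Data frame with columns `complete` (logical),
#'   `supplement_data_present` (logical) and `energy_kcal`.
#' @return List with `kept` (records passing all filters) and `excluded`
#'   (the rest, with an added `reason` column); together they partition the
#'   input.
#' @export
apply_exclusions <- function(records) {
  req <- c("complete", "supplement_data_present", "energy_kcal")
  if (!all(req %in% names(records)))
    stop("'records' must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  reason <- rep(NA_character_, nrow(records))
  rules <- list(
    incomplete_diet = !records$complete,
    missing_supplement_data = !records$supplement_data_present,
    low_energy = records$energy_kcal < 500,
    high_energy = records$energy_kcal > 3500)
  for (nm in names(rules))
    reason[is.na(reason) & rules[[nm]]] <- nm
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Score an intake table into index values
#'
#' Applies [score_component()] for every component and sums the scores with
#' [compute_index()]. When `specs` is the per-country list returned by
#' [derive_caps()], each subject is scored against their own country's
#' cutoffs.
#'
#' @param intakes Data frame with `subject_id`, `country`, and one column
#'   per component.
#' @param specs List of [component_spec()] (shared across countries) or a
#'   per-country named list of such lists.
#' @return Data frame with `subject_id`, `country`, one score column per
#'   component, and the total `index`.
#' @export
score_intakes <- function(intakes, specs) {
  per_country <- !inherits(specs[[1]], "component_spec")
  template <- if (per_country) specs[[1]] else specs
  comp_names <- vapply(template, `[[`, character(1), "name")
  scores <- matrix(NA_real_, nrow(intakes), length(comp_names),
                   dimnames = list(NULL, comp_names))
  for (i in seq_len(nrow(intakes))) {
    sp_list <- if (per_country) {
      cty <- intakes$country[i]
      if (!cty %in% names(specs))
        stop("no component specs for country '", cty, "'", call. = FALSE)
      specs[[cty]]
    } else specs
    for (j in seq_along(sp_list))
      scores[i, j] <- score_component(intakes[[comp_names[j]]][i],
                                      sp_list[[j]])
  }
  out <- data.frame(subject_id = intakes$subject_id,
                    country = intakes$country, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  out$index <- compute_index(scores)
  out
}

#' Read / write component specifications as YAML
#'
#' The YAML layout is a top-level `components` list whose entries carry
#' `name`, `kind`, `full_score_cutoff`, `zero_score_cutoff` and optionally
#' `cap_rule` (`percentile`, `target`). An illustrative 16-component file
#' ships in `system.file("extdata", "example_components.yaml", package =
#' "dietshrink")`; its cutoff values are placeholders for demonstration, not
#' published guideline constants.
#'
#' @param path File path.
#' @return `read_component_specs()` returns a list of [component_spec()]
#'   objects; `write_component_specs()` returns `path` invisibly.
#' @export
read_component_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$components))
    stop("YAML file must have a top-level 'components' list", call. = FALSE)
  lapply(raw$components, function(x)
    component_spec(x$name, x$kind, x$full_score_cutoff, x$zero_score_cutoff,
                   cap_rule = x$cap_rule))
}

#' @rdname read_component_specs
#' @param specs List of [component_spec()] objects.
#' @export
write_component_specs <- function(specs, path) {
  yaml::write_yaml(list(components = lapply(specs, unclass)), path)
  invisible(path)
}

#' Illustrative 16-component specification
#'
#' Loads the example component file shipped with the package: the 16
#' component names of the index (adequacy components for fruits,
#' vegetables, legumes, low-fat dairy, low-fat cheese, fish, low-fat meat
#' and poultry, nuts, olive oil, fluids and vitamin D supplementation;
#' range components for whole grains and eggs; limit components for
#' alcohol, sodium and sweets) with placeholder cutoffs. The published
#' guideline cut-off constants live in the dietary-guideline reference, not
#' here; real analyses should supply their own file.
#'
#' @return A list of 16 [component_spec()] objects.
#' @export
example_component_specs <- function() {
  read_component_specs(system.file("extdata", "example_components.yaml",
                                   package = "dietshrink", mustWork = TRUE))
}
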