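#' Read a single-compound acute bioassay table
#'
#' Reads and validates `singles.csv`-style input with columns
#' `compound,conc_mg_L,n_exposed,n_dead,replicate`. Concentrations must
#' already be in mg/L; a `unit` column, if present, must say `mg/L` (or
#' `mg L-1`) for every row.
#'
#' @param path CSV file path.
#' @return Validated data frame of mortality records.
#' @export
read_singles <- function(path) {
  d <- .read_csv_checked(path, c("compound", "conc_mg_L", "n_exposed",
                                 "n_dead", "replicate"))
  mortality_records(d)
}

#' Read a binary-mixture trial table
#'
#' Summary form: columns `compound_a,compound_b,tu_a,tu_b,obs_mean_pct,
#' obs_sd_pct,n_reps`. Long form (per-replicate): the same identifiers
#' with `obs_pct` instead of the summary columns; replicates are then
#' summarised to mean/SD/n.
#'
#' @param path CSV file path.
#' @return Data frame in summary form.
#' @export
read_mixtures <- function(path) {
  d <- .read_csv_checked(path, c("compound_a", "compound_b", "tu_a", "tu_b"))
  if ("obs_pct" %in% names(d)) {
    agg <- stats::aggregate(obs_pct ~ compound_a + compound_b + tu_a + tu_b,
                            data = d,
                            FUN = function(v) c(m = mean(v), s = stats::sd(v),
                                                n = length(v)))
    out <- agg[, c("compound_a", "compound_b", "tu_a", "tu_b")]
    out$obs_mean_pct <- agg$obs_pct[, "m"]
    out$obs_sd_pct <- agg$obs_pct[, "s"]
    out$n_reps <- as.integer(agg$obs_pct[, "n"])
    d <- out
  } else {
    miss <- setdiff(c("obs_mean_pct", "obs_sd_pct", "n_reps"), names(d))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(d$tu_a < 0 | d$tu_b < 0))
    stop("TU fractions must be >= 0", call. = FALSE)
  if (any(d$obs_mean_pct < 0 | d$obs_mean_pct > 100))
    stop("obs_mean_pct must be in [0, 100]", call. = FALSE)
  d
}

#' Read a biomarker measurement table
#'
#' Expects `endpoint,treatment,bio_replicate,tech_replicate,value,unit`
#' (tech_replicate and unit optional) and returns one
#' [biomarker_panel()] per endpoint.
#'
#' @param path CSV file path.
#' @return Named list of panels.
#' @export
read_biomarkers <- function(path) {
  d <- .read_csv_checked(path, c("endpoint", "treatment", "bio_replicate",
                                 "value"))
  sp <- split(d, d$endpoint)
  stats::setNames(lapply(names(sp), function(e) {
    unit <- if ("unit" %in% names(sp[[e]])) sp[[e]]$unit[1] else ""
    biomarker_panel(sp[[e]], endpoint = e, unit = unit)
  }), names(sp))
}

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no records in ", path, call. = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("unit" %in% names(d)) {
    ok <- grepl("^mg ?/? ?L", d$unit) | d$unit == ""
    if (!all(ok))
      stop("concentration units must be mg/L (row ",
           which(!ok)[1], " has '", d$unit[which(!ok)[1]], "')",
           call. = FALSE)
  }
  num <- intersect(required, names(d))
  for (cn in num) {
    if (cn %in% c("compound", "replicate", "endpoint", "treatment",
                  "compound_a", "compound_b")) next
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !is.na(d[[cn]]))
    if (length(bad))
      stop("malformed numeric cell in ", basename(path), " column ", cn,
           " row ", bad[1], call. = FALSE)
    d[[cn]] <- v
  }
  d
}

#' Run the full mixture-toxicity analysis pipeline
#'
#' Orchestrates the standard sequence on file inputs: fit single-
#' compound curves and tabulate LC20/LC50 (with delta-method CIs),
#' compute effect-summation expectations and interaction calls for each
#' binary mixture, run the CA- and IA-based deviation-model ladders, and
#' (optionally) the biomarker statistics. All outputs are written to
#' `out_dir` as CSV/JSON at full precision together with a run log
#' recording the configuration, seed, package version and convergence
#' flags; identical inputs and seed give bit-identical reports.
#'
#' @param singles Path to the single-compound CSV (see [read_singles()]).
#' @param mixtures Path to the mixture CSV (see [read_mixtures()]);
#'   optional.
#' @param biomarkers Path to the biomarker CSV; optional.
#' @param out_dir Output directory (created if needed).
#' @param fit_method Estimator for [fit_dose_response()].
#' @param refit_curves Refit single-compound curves inside the surface
#'   models (default TRUE, appropriate when the surface is fitted to
#'   mixture means only).
#' @param alpha Significance level for interaction calls and the model
#'   ladder.
#' @param seed Integer seed recorded in the log (the analysis itself is
#'   deterministic; the seed feeds any downstream simulation).
#' @return Invisible list with elements `lc_table`, `mixture_tables`,
#'   `surface_selections`, `biomarker_reports`, `log`.
#' @export
run_pipeline <- function(singles, mixtures = NULL, biomarkers = NULL,
                         out_dir = ".",
                         fit_method = c("binomial_glm", "empirical_logit_ols"),
                         refit_curves = TRUE, alpha = 0.05, seed = 1L) {
  fit_method <- match.arg(fit_method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package = "cilitox",
              version = as.character(utils::packageVersion("cilitox")),
              fit_method = fit_method, refit_curves = refit_curves,
              alpha = alpha, seed = as.integer(seed),
              interaction_test = "one-sample two-sided t vs effect-summation expectation",
              ia_deviation_convention = "survival product ^ exp(-G); a < 0 synergistic",
              component_order = NULL, warnings = character(0))

  recs <- read_singles(singles)
  fits <- lapply(split(recs, recs$compound), fit_dose_response,
                 method = fit_method)
  lc <- lc_table(fits)
  utils::write.csv(lc, file.path(out_dir, "lc_table.csv"), row.names = FALSE)
  fit_report <- lapply(fits, function(f)
    list(alpha = f$curve$alpha, beta = f$curve$beta,
         covariance = unclass(f$vcov), r_squared = f$r_squared,
         method = f$method, converged = f$converged))
  jsonlite::write_json(fit_report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)

  mixture_tables <- list(); selections <- list()
  if (!is.null(mixtures)) {
    mx <- read_mixtures(mixtures)
    pairs <- unique(mx[, c("compound_a", "compound_b")])
    for (i in seq_len(nrow(pairs))) {
      ka <- pairs$compound_a[i]; kb <- pairs$compound_b[i]
      if (!ka %in% names(fits) || !kb %in% names(fits))
        stop("mixture components ", ka, "/", kb,
             " lack single-compound fits", call. = FALSE)
      sub <- mx[mx$compound_a == ka & mx$compound_b == kb, ]
      comp_a <- tu_component(fits[[ka]]$curve, compound = ka)
      comp_b <- tu_component(fits[[kb]]$curve, compound = kb)
      tab <- tu_mixture_analysis(sub, comp_a, comp_b, alpha = alpha)
      key <- paste0(ka, "+", kb)
      mixture_tables[[key]] <- tab
      dat <- data.frame(c1 = sub$tu_a * comp_a$lc50_ref,
                        c2 = sub$tu_b * comp_b$lc50_ref,
                        obs = sub$obs_mean_pct / 100)
      selections[[key]] <- lapply(
        c(CA = "CA", IA = "IA"),
        function(ref) model_selection(dat, ref, fits[[ka]]$curve,
                                      fits[[kb]]$curve,
                                      refit_curves = refit_curves,
                                      alpha = alpha))
      utils::write.csv(tab,
                       file.path(out_dir, paste0("mixture_table_", ka, "_",
                                                 kb, ".csv")),
                       row.names = FALSE)
      surf <- do.call(rbind, lapply(selections[[key]], `[[`, "table"))
      utils::write.csv(surf,
                       file.path(out_dir, paste0("surface_report_", ka, "_",
                                                 kb, ".csv")),
                       row.names = FALSE)
    }
    log$component_order <- paste(pairs$compound_a, pairs$compound_b,
                                 sep = "+")
  }

  biomarker_reports <- NULL
  if (!is.null(biomarkers)) {
    panels <- read_biomarkers(biomarkers)
    biomarker_reports <- lapply(panels, function(p)
      list(endpoint = attr(p, "endpoint"),
           assumptions = unclass(assumption_checks(p, alpha)),
           anova = unclass(anova_bonferroni(p, alpha))))
    if (length(panels) >= 2L) {
      cm <- correlation_matrix(panels)
      utils::write.csv(as.data.frame(cm),
                       file.path(out_dir, "correlations.csv"))
    }
    jsonlite::write_json(biomarker_reports,
                         file.path(out_dir, "biomarker_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(lc_table = lc, mixture_tables = mixture_tables,
                 surface_selections = selections,
                 biomarker_reports = biomarker_reports, log = log))
}
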