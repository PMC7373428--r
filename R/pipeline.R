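#' Read and validate a delimited source table
#'
#' Schema-validated CSV reader for the tables the pipeline consumes.
#' Column names are normalized to lower case; unrecognized columns are
#' preserved untouched; rows failing validation are reported with their
#' row numbers.
#'
#' @param path CSV file path.
#' @param schema one of \code{"cohort"} (animal_id, replicate, arm, day,
#'   event), \code{"proportions"} (group, successes, trials),
#'   \code{"measurements"} (value, group).
#' @return The validated data frame (a \code{lifespan_cohort} for the
#'   cohort schema).
#' @export
read_source_table <- function(path,
                              schema = c("cohort", "proportions",
                                         "measurements")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stopf("input file not found: %s", path)
  if (schema == "cohort") return(read_cohort_csv(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  req <- switch(schema,
                proportions = c("group", "successes", "trials"),
                measurements = c("value", "group"))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("missing mandatory column(s) %s; expected schema: %s",
          paste(miss, collapse = ", "), paste(req, collapse = ", "))
  if (schema == "proportions") {
    bad <- which(df$successes < 0 | df$successes > df$trials)
    if (length(bad)) stopf("successes outside [0, trials] at row(s) %s",
                           paste(bad, collapse = ", "))
  }
  df
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order on either synthetic
#' inputs (generator configs) or supplied cohort CSVs, writes result
#' tables under \code{out_dir}, and returns a machine-readable run report
#' with a provenance block (seed, package version, per-stage status).
#' A failed stage is recorded as failed and does not abort the others.
#'
#' @param config a list with fields \code{seed}, \code{out_dir}, and any
#'   of: \code{lifespan} (a \code{lifespan_sim_config} or a cohort CSV
#'   path), \code{xfm} (an \code{xfm_sim_config}), \code{xanes} (an
#'   \code{xanes_sim_config}), \code{dose} (a \code{dose_sim_config}).
#'   Optional \code{n_perm} (rescaling-test permutations, default 200).
#' @return A list of class \code{"run_report"} with per-stage results and
#'   a \code{provenance} block; also written as \code{report.json} in
#'   \code{out_dir} when one is given.
#' @export
run_pipeline <- function(config) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(stages = list(),
                 provenance = list(seed = seed,
                                   package = "ferroscale",
                                   version = as.character(
                                     utils::packageVersion("ferroscale")),
                                   r_version = R.version.string,
                                   timestamp = format(Sys.time())))
  run_stage <- function(name, fun) {
    res <- tryCatch(list(status = "ok", result = fun()),
                    error = function(e) list(status = "failed",
                                             error = conditionMessage(e)))
    report$stages[[name]] <<- res
    invisible(res)
  }
  if (!is.null(config$lifespan)) {
    run_stage("lifespan", function() {
      cohort <- if (is.character(config$lifespan)) {
        read_source_table(config$lifespan, "cohort")
      } else {
        cfg <- config$lifespan
        cfg$seed <- seed
        gen_lifespan(cfg)
      }
      if (!is.null(out_dir))
        write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
      arms <- levels(cohort$arm)
      km <- lapply(split(as.data.frame(cohort), cohort$arm),
                   function(d) km_curve(d$day, d$event))
      medians <- vapply(km, `[[`, numeric(1), "median")
      lr <- if (length(arms) > 1) logrank(cohort) else NULL
      reps <- split(as.data.frame(cohort), cohort$replicate)
      per_rep <- lapply(reps, function(d) {
        bj <- fit_buckley_james(d)
        ks <- ks_rescaling_test(bj, n_perm = config$n_perm %||% 200,
                                seed = seed)
        sel <- lrt_select(d)
        list(bj_coef = coef(bj), ks_D = ks$D, ks_p = ks$p,
             best_model = sel$best$model_label,
             params = coef(sel$best))
      })
      ks_pooled <- fisher_combine(vapply(per_rep, `[[`, 1, "ks_p"))
      meta <- NULL
      if (length(reps) >= 2) {
        fits <- lapply(reps, fit_weibull_gamma)
        nm <- Reduce(intersect, lapply(fits, function(f) names(f$params)))
        meta <- lapply(setNames(nm, nm), function(pn) {
          ests <- vapply(fits, function(f) f$params[[pn]], 1)
          vs <- vapply(fits, function(f) f$covariance[pn, pn], 1)
          if (any(!is.finite(vs) | vs <= 0)) return(NULL)
          m <- meta_combine(ests, vs, "fixed", parameter = pn)
          list(estimate = m$estimate, se = m$se, Q = m$Q)
        })
      }
      tabs <- list(km_medians = medians, logrank = lr,
                   per_replicate = per_rep, ks_pooled = ks_pooled,
                   meta_fixed = meta)
      if (!is.null(out_dir)) {
        md <- data.frame(arm = names(medians), median = unname(medians))
        utils::write.csv(md, file.path(out_dir, "km_medians.csv"),
                         row.names = FALSE)
      }
      tabs
    })
  }
  if (!is.null(config$xfm)) {
    run_stage("xfm", function() {
      cfg <- config$xfm; cfg$seed <- seed
      scene <- gen_xfm_scene(cfg)
      rois <- segment_compton(scene,
                              min_pixels = config$min_pixels %||% 10000)
      bg <- scene$channels$Fe[!rois$pre_filter_foreground]
      cur <- currie_threshold(bg)
      fac <- sim_truth(scene)$fe_factor_ugcm2
      tab <- quantify_rois(scene, rois, fac, cur)
      if (!is.null(out_dir))
        utils::write.csv(tab, file.path(out_dir, "worm_iron.csv"),
                         row.names = FALSE)
      list(n_rois = length(rois$roi_ids), results = tab)
    })
  }
  if (!is.null(config$xanes)) {
    run_stage("xanes", function() {
      cfg <- config$xanes; cfg$seed <- seed
      stack <- gen_xanes_stack(cfg)
      stack <- align_stack(stack)
      roi <- cfg$iron_density_map > 0
      sp <- extract_normalized_spectrum(stack, roi)
      pe <- fit_pre_edge(sp)
      cal <- speciation_calibration(endmembers = cfg$endmembers,
                                    grid = cfg$grid)
      fr <- estimate_fe2_fraction(pe, sp, cal, mode = "centroid",
                                  n_boot = config$n_boot %||% 100,
                                  seed = seed)
      if (!is.null(out_dir))
        utils::write.csv(data.frame(energy = sp$energies, mu = sp$mu),
                         file.path(out_dir, "spectrum.csv"),
                         row.names = FALSE)
      list(centroid = pe$centroid, fe2_fraction = fr$fe2_fraction,
           ci95 = fr$ci95)
    })
  }
  if (!is.null(config$dose)) {
    run_stage("dose", function() {
      cfg <- config$dose; cfg$seed <- seed
      d <- gen_dose_response(cfg)
      fit <- fit_sigmoid(d)
      agg <- aggregate(dead ~ dose, d, function(x) c(sum(x), length(x)))
      ci <- t(vapply(seq_len(nrow(agg)), function(i) {
        w <- wilson_ci(agg$dead[i, 1], agg$dead[i, 2])
        c(w$estimate, w$lower, w$upper)
      }, numeric(3)))
      props <- data.frame(dose = agg$dose, proportion = ci[, 1],
                          lower = ci[, 2], upper = ci[, 3])
      if (!is.null(out_dir))
        utils::write.csv(props, file.path(out_dir, "dose_response.csv"),
                         row.names = FALSE)
      list(ld50 = fit$ld50, hill = fit$hill, proportions = props)
    })
  }
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    clean <- rapply(unclass(report), function(x)
      if (is.function(x) || inherits(x, "lm")) NULL else x, how = "replace")
    jsonlite::write_json(clean, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$stages))
    cat(sprintf("  %s: %s\n", nm, x$stages[[nm]]$status))
  cat(sprintf("  seed %d, ferroscale %s\n", x$provenance$seed,
              x$provenance$version))
  invisible(x)
}
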