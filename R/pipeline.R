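# Config-driven end-to-end runs: simulate -> tracts -> pulse fitting ->
# sex bias, with provenance and a machine-readable report.

#' Paper-derived analysis defaults
#'
#' The conventional constants used across the pipeline, collected in one
#' place: tract-class boundaries 5 and 50 cM, founding depth 15
#' generations, 29 years per generation, ancestry-masking inclusion
#' thresholds (40% EUR / 75% AFR / 15% NAM), and the 3 cM IBD floor.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(short_min_cM = 5, short_max_cM = 50, G0 = 15, gen_time = 29,
       mask_thresholds = c(EUR = 0.40, AFR = 0.75, NAM = 0.15),
       ibd_min_cM = 3, het_window_cM = 0.5)
}

config_template <- function() {
  list(out_dir = NULL,
       simulate = list(seed = NULL, n_hap = NULL, n_ind = NULL,
                       pop_size = 2000, sexed = FALSE, founding = NULL,
                       founding_female = NULL, founding_male = NULL,
                       T_max = 15, pulses = NULL,
                       map = list(n_autosomes = 5, autosome_M = 1,
                                  include_x = FALSE, x_M = 1.8)),
       tracts = list(enabled = TRUE),
       pulsefit = list(enabled = FALSE, models = c("M1", "M2"),
                       n_restarts = 100, seed = NULL, G0 = 15,
                       gen_time = 29, anchor_year = NULL),
       sexbias = list(enabled = FALSE, seed = NULL, B = 1000))
}

check_keys <- function(cfg, tmpl, path = "config") {
  unknown <- setdiff(names(cfg), names(tmpl))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg))
    if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) &&
        is.list(cfg[[k]]) && !is.data.frame(cfg[[k]]) &&
        !(k %in% c("pulses", "founding", "founding_female",
                   "founding_male", "mask_thresholds")))
      check_keys(cfg[[k]], tmpl[[k]], paste0(path, "$", k))
  invisible(cfg)
}

#' Run the pipeline described by a configuration
#'
#' Stages execute in dependency order (simulate, tract statistics, pulse
#' fitting, sex bias); a stage failure halts the run with a stage-tagged
#' error.  Every stochastic stage requires an explicit seed, unknown
#' configuration keys are rejected, and all written artifacts are
#' checksummed in the report, so identical configurations give identical
#' outputs.
#'
#' @param config nested list (see `admixtract:::config_template()` for the
#'   schema), or the path of a YAML file holding one.
#' @return object of class `run_report` (also written to
#'   `<out_dir>/run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  check_keys(config, config_template())
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "admixtract",
                 version = as.character(utils::packageVersion("admixtract")),
                 defaults = pipeline_defaults(), stages = list())
  files <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    keep <- res[setdiff(names(res), "value")]
    report$stages[[name]] <<- c(keep, list(
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3)))
    res
  }
  out <- function(f) file.path(config$out_dir, f)

  # -- simulate -------------------------------------------------------
  sc <- config$simulate
  if (is.null(sc$seed)) stop("config$simulate$seed is required")
  mp <- modifyList(config_template()$simulate$map,
                   if (is.null(sc$map)) list() else sc$map)
  map <- toy_genetic_map(mp$n_autosomes, mp$autosome_M, mp$include_x,
                         mp$x_M)
  pulses <- if (!is.null(sc$pulses)) {
    p <- sc$pulses
    if (!is.data.frame(p)) p <- do.call(rbind, lapply(p, as.data.frame))
    p
  }
  cohort <- stage("simulate", {
    if (isTRUE(sc$sexed)) {
      hist <- build_history(list(female = unlist(sc$founding_female),
                                 male = unlist(sc$founding_male)),
                            T_max = sc$T_max, pulses = pulses)
      co <- simulate_sexed_cohort(hist, map, n_ind = sc$n_ind,
                                  pop_size = sc$pop_size, seed = sc$seed)
      write_metadata_tsv(co$individuals, out("metadata.tsv"))
    } else {
      hist <- build_history(unlist(sc$founding), T_max = sc$T_max,
                            pulses = pulses)
      co <- simulate_tracts(hist, map, n_hap = sc$n_hap,
                            pop_size = sc$pop_size, seed = sc$seed)
    }
    write_tracts_tsv(co$tracts, out("tracts.tsv"))
    files <<- c(files, out("tracts.tsv"))
    list(seed = sc$seed, n_tracts = nrow(co$tracts), value = co)
  })$value

  auto_tracts <- cohort$tracts
  if (!is.null(auto_tracts$compartment)) {
    full <- auto_tracts
    auto_tracts <- as_tract_set(
      as.data.frame(full[full$compartment == "auto", ]),
      attr(full, "chrom_lengths_cM")[
        names(attr(full, "chrom_lengths_cM")) !=
          cohort$map$chrom[cohort$map$is_x]],
      n_hap = attr(full, "n_hap"))
  }

  # -- tract statistics ----------------------------------------------
  if (isTRUE(config$tracts$enabled) || is.null(config$tracts)) {
    stage("tracts", {
      props <- global_proportions(auto_tracts, "individual")
      write.table(data.frame(individual = rownames(props), props,
                             check.names = FALSE),
                  out("ancestry_proportions.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      cls <- tract_class_stats(auto_tracts)
      write.table(cls$composition, out("tract_class_composition.csv"),
                  sep = ",", row.names = FALSE, quote = FALSE)
      write.table(cls$split, out("tract_class_split.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      files <<- c(files, out("ancestry_proportions.csv"),
                  out("tract_class_composition.csv"),
                  out("tract_class_split.csv"))
      list(n_individuals = nrow(props))
    })
  }

  # -- pulse-model fitting -------------------------------------------
  if (isTRUE(config$pulsefit$enabled)) {
    pc <- modifyList(config_template()$pulsefit, config$pulsefit)
    if (is.null(pc$seed)) stop("config$pulsefit$seed is required")
    stage("pulsefit", {
      h <- tract_histogram(auto_tracts)
      fits <- lapply(pc$models, function(id)
        fit_pulse_model(h, id, n_restarts = pc$n_restarts, seed = pc$seed,
                        G0 = pc$G0, anchor_year = pc$anchor_year,
                        gen_time = pc$gen_time))
      cmp <- compare_models(fits)
      write.table(as.data.frame(cmp), out("model_comparison.csv"),
                  sep = ",", row.names = FALSE, quote = FALSE)
      best <- fits[[match(cmp$model[1], vapply(fits, function(f)
        f$model$id, ""))]]
      fit_json <- list(model = best$model$id,
                       logLik = best$logLik,
                       coefficients = as.list(coef(best)))
      if (!is.null(pc$anchor_year)) {
        np <- nrow(best$model$pulses)
        fit_json$pulse_years_CE <- as.list(setNames(
          generations_to_years(coef(best)[2 * seq_len(np)],
                               pc$anchor_year, pc$gen_time),
          best$model$pulses$label))
      }
      jsonlite::write_json(fit_json, out("best_fit.json"),
                           auto_unbox = TRUE, digits = 10)
      files <<- c(files, out("model_comparison.csv"), out("best_fit.json"))
      list(seed = pc$seed, best_model = cmp$model[1],
           logLik = cmp$logLik[1])
    })
  }

  # -- sex bias -------------------------------------------------------
  if (isTRUE(config$sexbias$enabled)) {
    bc <- modifyList(config_template()$sexbias, config$sexbias)
    if (is.null(bc$seed)) stop("config$sexbias$seed is required")
    stage("sexbias", {
      if (is.null(cohort$tracts$compartment))
        stop("sex-bias stage needs a sexed simulation")
      ca <- compartment_ancestry(cohort)
      da <- delta_admix(ca, B = bc$B, seed = bc$seed)
      inv <- invert_sex_contributions(setNames(da$q_auto, da$ancestry),
                                      setNames(da$q_x, da$ancestry))
      write.table(as.data.frame(da), out("delta_admix.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      write.table(inv, out("sex_contributions.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      files <<- c(files, out("delta_admix.csv"),
                  out("sex_contributions.csv"))
      if (any(inv$clipped))
        warning("clipped sex contributions for: ",
                paste(inv$ancestry[inv$clipped], collapse = ", "))
      list(seed = bc$seed, n_individuals = attr(da, "n"))
    })
  }

  report$artifacts <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), out("run_report.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("admixtract pipeline run (version", x$version, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %6.2fs\n", nm, x$stages[[nm]]$elapsed_s))
  cat("  artifacts:", nrow(x$artifacts), "files\n")
  invisible(x)
}
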