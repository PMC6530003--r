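# One-shot orchestration: simulate -> extract -> evaluate, with config
# validation, child-seed derivation, and a self-describing manifest.

config_schema <- list(
  cohort = c("n_benign", "n_malignant", "spacing", "with_images"),
  extraction = c("bin_width", "calcification_hu_threshold", "sd_divisor"),
  evaluation = c("panel"),
  seed = NULL,
  out_dir = NULL
)

#' Default run configuration
#'
#' Study-sized cohort (71 benign / 61 malignant), 0.8 mm pixel spacing,
#' 1-HU entropy bins, 300 HU calcification exclusion, population-SD
#' divisor, and the default cutoff panel.
#'
#' @param seed integer seed for the whole run.
#' @param out_dir output directory.
#' @return nested list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("nodetex_run")) {
  list(
    seed = seed,
    out_dir = out_dir,
    cohort = list(n_benign = 71L, n_malignant = 61L, spacing = 0.8,
                  with_images = TRUE),
    extraction = list(bin_width = 1, calcification_hu_threshold = 300,
                      sd_divisor = "population"),
    evaluation = list(panel = default_panel())
  )
}

validate_config <- function(config, schema = config_schema, path = "") {
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (key in names(config)) {
    allowed <- schema[[key]]
    if (!is.null(allowed) && is.list(config[[key]]) && key != "evaluation") {
      bad <- setdiff(names(config[[key]]), allowed)
      if (length(bad)) {
        stop("unknown config key(s): ",
             paste0(path, key, ".", bad, collapse = ", "))
      }
    }
  }
  if (is.null(config$seed)) stop("config must set a seed")
  invisible(config)
}

# Deterministic per-stage child seeds: stages are independently
# re-runnable and adding a stage never shifts another stage's stream.
stage_seed <- function(seed, stage) {
  k <- match(stage, c("simulate", "extract", "evaluate"))
  as.integer((as.numeric(seed) + 48271 * k) %% 2147483647)
}

# Order-insensitive-enough FNV-1a hash of the JSON-serialized config,
# for manifest change detection.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the simulate -> extract -> evaluate pipeline
#'
#' Executes the three stages in order under a single seed (fanned out to
#' per-stage child seeds), writing the cohort, the CTTA feature table,
#' the group-comparison table, and the ROC panel under `out_dir`, plus a
#' JSON manifest recording the config hash, seed, every
#' otherwise-implicit default (bin width, exclusion threshold, SD
#' divisor), the file inventory and per-stage status. A stage failure
#' halts the run and the manifest marks the failed stage.
#'
#' @param config nested list as from [default_run_config()], or a path to
#'   a YAML file with the same structure.
#' @return path of the manifest JSON, invisibly; the manifest list as
#'   attribute `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list(simulate = "pending", extract = "pending",
                 evaluate = "pending")
  files <- list()
  manifest_path <- file.path(out_dir, "run_manifest.json")
  write_manifest <- function() {
    manifest <- list(
      config_hash = config_hash(config),
      seed = config$seed,
      defaults = config$extraction,
      spacing = config$cohort$spacing,
      stages = status,
      files = files,
      package_version = as.character(packageVersion("nodetex"))
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest
  }

  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) {
      status[[stage]] <<- paste("failed:", conditionMessage(e))
      write_manifest()
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    status[[stage]] <<- "ok"
    res
  }

  cohort <- run_stage("simulate", function() {
    set.seed(stage_seed(config$seed, "simulate"))
    co <- generate_cohort(
      n_benign = config$cohort$n_benign,
      n_malignant = config$cohort$n_malignant,
      spacing = config$cohort$spacing,
      with_images = isTRUE(config$cohort$with_images)
    )
    co$seed <- stage_seed(config$seed, "simulate")
    if (!is.null(co$nodes)) {
      write_cohort(co, file.path(out_dir, "cohort"))
      files$cohort <<- file.path("cohort", "manifest.json")
    }
    rec_f <- file.path(out_dir, "records.csv")
    write.csv(co$records, rec_f, row.names = FALSE)
    files$records <<- basename(rec_f)
    co
  })

  features <- run_stage("extract", function() {
    if (is.null(cohort$nodes)) return(NULL)
    set.seed(stage_seed(config$seed, "extract"))
    feats <- extract_all(
      cohort,
      rules = exclusion_rules(config$extraction$calcification_hu_threshold),
      binning = bin_spec(config$extraction$bin_width),
      sd_divisor = config$extraction$sd_divisor
    )
    f <- file.path(out_dir, "features.csv")
    write.csv(feats, f, row.names = FALSE)
    files$features <<- basename(f)
    feats
  })

  run_stage("evaluate", function() {
    set.seed(stage_seed(config$seed, "evaluate"))
    tab <- cohort$records
    if (!is.null(features)) {
      tab <- merge(tab, features[setdiff(names(features), "label")],
                   by = "node_id", sort = TRUE)
    }
    comp <- summarize_table(tab,
                            setdiff(names(tab)[vapply(tab, function(x)
                              is.numeric(x) || is.logical(x), logical(1))],
                              "node_id"))
    f1 <- file.path(out_dir, "comparisons.csv")
    write.csv(comp, f1, row.names = FALSE)
    files$comparisons <<- basename(f1)
    panel <- Filter(function(e) {
      cols <- if (!is.null(e$all_of)) {
        vapply(e$all_of, function(x) x$feature, "")
      } else e$feature
      all(cols %in% names(tab))
    }, config$evaluation$panel)
    pan <- evaluate_panel(tab, panel)
    f2 <- file.path(out_dir, "roc_panel.csv")
    write.csv(pan, f2, row.names = FALSE)
    files$roc_panel <<- basename(f2)
    invisible(NULL)
  })

  manifest <- write_manifest()
  out <- manifest_path
  attr(out, "manifest") <- manifest
  invisible(out)
}

#' Render a plain-text report from a completed run
#'
#' Prints the class sizes, the group-comparison table (count (%) or
#' mean +/- SD per class with p-values, percentages at one decimal, AUCs
#' at three) and the ROC panel from a run directory's CSVs. Missing stage
#' outputs degrade to a partial report with a warning.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the printed lines, invisibly.
#' @export
render_report <- function(run_dir) {
  lines <- character()
  say <- function(...) lines <<- c(lines, sprintf(...))
  man_f <- file.path(run_dir, "run_manifest.json")
  if (file.exists(man_f)) {
    man <- jsonlite::read_json(man_f, simplifyVector = TRUE)
    say("nodetex run %s (seed %s)", man$config_hash, man$seed)
    say("defaults: bin width %s HU, exclusion > %s HU, SD divisor %s",
        man$defaults$bin_width, man$defaults$calcification_hu_threshold,
        man$defaults$sd_divisor)
  }
  rec_f <- file.path(run_dir, "records.csv")
  if (file.exists(rec_f)) {
    rec <- read.csv(rec_f)
    say("cohort: %d benign / %d malignant nodes",
        sum(rec$label == "benign"), sum(rec$label == "malignant"))
  }
  comp_f <- file.path(run_dir, "comparisons.csv")
  if (file.exists(comp_f)) {
    comp <- read.csv(comp_f)
    say("")
    say("%-22s %-22s %-22s %8s", "feature", "benign", "malignant", "p")
    for (i in seq_len(nrow(comp))) {
      r <- comp[i, ]
      fmt <- function(side) {
        if (r$type == "binary") {
          sprintf("%d (%.1f)", r[[paste0("count_", side)]],
                  r[[paste0("pct_", side)]])
        } else {
          sprintf("%.1f +/- %.1f", r[[paste0("mean_", side)]],
                  r[[paste0("sd_", side)]])
        }
      }
      say("%-22s %-22s %-22s %8s", r$feature, fmt("benign"),
          fmt("malignant"),
          if (is.na(r$p_value)) "-" else sprintf("%.3f", r$p_value))
    }
  } else {
    warning("comparisons.csv missing; report is partial")
    say("[group comparisons unavailable]")
  }
  pan_f <- file.path(run_dir, "roc_panel.csv")
  if (file.exists(pan_f)) {
    pan <- read.csv(pan_f)
    say("")
    say("%-22s %6s %6s %13s %7s %7s", "variable", "AUC", "SE",
        "95% CI", "Se(%)", "Sp(%)")
    for (i in seq_len(nrow(pan))) {
      r <- pan[i, ]
      say("%-22s %6.3f %6.3f %6.3f-%6.3f %7.1f %7.1f", r$name, r$auc,
          r$se_auc, r$ci_lo, r$ci_hi, r$sensitivity, r$specificity)
    }
  } else {
    warning("roc_panel.csv missing; report is partial")
    say("[ROC panel unavailable]")
  }
  if (!file.exists(file.path(run_dir, "features.csv"))) {
    say("[CTTA feature block unavailable: extraction outputs missing]")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
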