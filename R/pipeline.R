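#' Build a validated pipeline configuration
#'
#' @param model a [metabolic_network()] or a path to an SBML file.
#' @param expr an [expression_matrix()] (already constructed), or `NULL` if
#'   `counts` paths are given.
#' @param counts optional named list of paths (`mtx`, `genes`, `barcodes`,
#'   `coords`, optionally `annotation`) passed to [read_expression_mtx()].
#' @param medium_bound open-medium magnitude (default 1000).
#' @param imputation `"none"` or `"magic"`.
#' @param method flux layers to compute: `"cb3"`, `"pfba"` or `"both"`.
#' @param n_samples CB3 samples per spot (default 10000).
#' @param ci_level FES confidence level (default 0.99).
#' @param seed integer seed (mandatory; drives sampling and clustering).
#' @param target_sum library-size normalisation target.
#' @param outdir output directory for stage artifacts and the manifest;
#'   `NULL` keeps everything in memory.
#' @param overwrite if `FALSE` (default) cached stage outputs in `outdir`
#'   are reused.
#' @return an object of class `run_config`.
#' @export
run_config <- function(model, expr = NULL, counts = NULL, medium_bound = 1000,
                       imputation = "none", method = c("cb3", "pfba", "both"),
                       n_samples = 10000, ci_level = 0.99, seed,
                       target_sum = 1e4, outdir = NULL, overwrite = FALSE) {
  method <- match.arg(method)
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  if (is.character(model) && !file.exists(model)) stop("model path not found: ", model)
  if (is.null(expr) && is.null(counts)) stop("either expr or counts must be given")
  if (!is.null(counts)) {
    need <- c("mtx", "genes", "barcodes", "coords")
    if (!all(need %in% names(counts))) stop("counts must name mtx/genes/barcodes/coords")
    missing_f <- unlist(counts)[!file.exists(unlist(counts))]
    if (length(missing_f)) stop("count file(s) not found: ", paste(missing_f, collapse = ", "))
  }
  cfg <- list(model = model, expr = expr, counts = counts,
              medium_bound = medium_bound, imputation = imputation,
              method = method, n_samples = n_samples, ci_level = ci_level,
              seed = as.integer(seed), target_sum = target_sum,
              outdir = outdir, overwrite = overwrite)
  class(cfg) <- "run_config"
  cfg
}

stage_cache <- function(cfg, name, compute) {
  if (is.null(cfg$outdir)) return(compute())
  path <- file.path(cfg$outdir, paste0(name, ".rds"))
  if (!cfg$overwrite && file.exists(path)) return(readRDS(path))
  val <- compute()
  saveRDS(val, path)
  val
}

#' Run the spatial flux pipeline end-to-end
#'
#' Orchestrates preprocess -> RAS -> FVA -> spot bounds -> vertex sampling
#' and/or pFBA -> FES, writing stage artifacts and a JSON manifest (inputs,
#' seed, file hashes, sampler skip counts) to `outdir` when given. Stages
#' cached in `outdir` are reused on re-runs unless `overwrite = TRUE`, so
#' deleting a late artifact and re-running recomputes only that stage.
#'
#' @param cfg a [run_config()].
#' @return an object of class `spfba_result`: list with `expr`, `network`,
#'   `ras`, `fva`, `bounds`, `fes` (CB3 layer or `NULL`), `pfba_fes`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir))
    dir.create(cfg$outdir, recursive = TRUE)

  network <- if (is.character(cfg$model)) load_model(cfg$model) else cfg$model
  network <- apply_open_medium(network, cfg$medium_bound)

  expr <- stage_cache(cfg, "preprocess", function() {
    e <- if (!is.null(cfg$expr)) cfg$expr else
      read_expression_mtx(cfg$counts$mtx, cfg$counts$genes, cfg$counts$barcodes,
                          cfg$counts$coords, cfg$counts$annotation)
    e <- normalize_counts(e, cfg$target_sum)
    if (!identical(cfg$imputation, "none"))
      e <- impute_expression(e, cfg$imputation)
    e
  })

  ras <- stage_cache(cfg, "ras", function() compute_ras_matrix(expr, network))
  fva <- stage_cache(cfg, "fva", function() run_fva(network))
  bounds <- stage_cache(cfg, "bounds", function() spot_bounds(fva, ras))

  spots <- bounds$spots
  set.seed(cfg$seed)
  spot_seeds <- stats::setNames(sample.int(.Machine$integer.max - 1, length(spots)),
                                spots)

  fes <- NULL; skip_counts <- NULL
  if (cfg$method %in% c("cb3", "both")) {
    summaries <- stage_cache(cfg, "samples_summary", function() {
      lapply(spots, function(s) {
        ss <- sample_cb3(network, bounds, s, n_samples = cfg$n_samples,
                         seed = spot_seeds[[s]], ranges = fva)
        list(spot = s, mean = colMeans(ss$samples),
             sd = apply(ss$samples, 2, stats::sd),
             n = nrow(ss$samples), n_failed = ss$n_failed)
      })
    })
    skip_counts <- vapply(summaries, `[[`, numeric(1), "n_failed")
    fes <- stage_cache(cfg, "fes", function() {
      rows <- lapply(summaries, function(sm) {
        z <- stats::qnorm((1 + cfg$ci_level) / 2)
        se <- sm$sd / sqrt(sm$n)
        f <- normalize_flux(sm$mean, fva$min, fva$max)
        lo <- normalize_flux(sm$mean - z * se, fva$min, fva$max)
        hi <- normalize_flux(sm$mean + z * se, fva$min, fva$max)
        list(fes = stats::setNames(f, names(sm$mean)),
             ci_low = stats::setNames(pmin(lo, hi, f), names(sm$mean)),
             ci_high = stats::setNames(pmax(lo, hi, f), names(sm$mean)),
             n_samples = sm$n)
      })
      fes_matrix(rows, spots, "cb3")
    })
  }

  pfba_fes <- NULL
  if (cfg$method %in% c("pfba", "both")) {
    pfba_fes <- stage_cache(cfg, "pfba_fes", function() {
      rows <- lapply(spots, function(s)
        fes_from_pfba(run_pfba(network, bounds, s), fva))
      fes_matrix(rows, spots, "pfba")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spfba")),
    seed = cfg$seed,
    medium_bound = cfg$medium_bound,
    imputation = cfg$imputation,
    method = cfg$method,
    n_samples = cfg$n_samples,
    ci_level = cfg$ci_level,
    n_spots = length(spots),
    n_reactions = length(network$rxns),
    sampler_skips = if (is.null(skip_counts)) 0 else sum(skip_counts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(cfg$outdir)) {
    write_result_tables(cfg$outdir, ras, fva, fes, pfba_fes)
    files <- list.files(cfg$outdir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$files <- stats::setNames(as.list(unname(tools::md5sum(files))),
                                      basename(files))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  class(manifest) <- c("spfba_manifest", class(manifest))

  out <- list(expr = expr, network = network, ras = ras, fva = fva,
              bounds = bounds, fes = fes, pfba_fes = pfba_fes,
              manifest = manifest)
  class(out) <- "spfba_result"
  out
}

write_result_tables <- function(outdir, ras, fva, fes, pfba_fes) {
  utils::write.csv(data.frame(reaction = fva$reaction, min = fva$min, max = fva$max),
                   file.path(outdir, "fva.csv"), row.names = FALSE)
  ras_df <- as.data.frame(ras$scores)
  ras_df <- cbind(spot = rownames(ras$scores), ras_df)
  utils::write.csv(ras_df, file.path(outdir, "ras.csv"), row.names = FALSE)
  long <- function(fm) {
    data.frame(spot = rep(fm$spots, times = length(fm$reactions)),
               reaction = rep(fm$reactions, each = length(fm$spots)),
               fes = as.vector(fm$scores),
               ci_low = as.vector(fm$ci_low),
               ci_high = as.vector(fm$ci_high))
  }
  if (!is.null(fes))
    utils::write.csv(long(fes), file.path(outdir, "fes_cb3.csv"), row.names = FALSE)
  if (!is.null(pfba_fes))
    utils::write.csv(long(pfba_fes), file.path(outdir, "fes_pfba.csv"), row.names = FALSE)
}

#' @export
print.spfba_manifest <- function(x, ...) {
  cat("spfba run manifest\n")
  for (nm in setdiff(names(x), "files"))
    cat(sprintf("  %-16s %s\n", nm, as.character(x[[nm]])))
  if (!is.null(x$files)) cat(sprintf("  %-16s %d artifact(s)\n", "files", length(x$files)))
  invisible(x)
}
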