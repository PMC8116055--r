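#' Assemble and validate a pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic capture (or NULL when
#'   `input_dir` points at an existing triplet-matrix trio)
#' @param input_dir optional directory containing matrix.mtx / features.tsv /
#'   barcodes.tsv to analyse instead of simulating
#' @param reference_path optional reference-profile TSV; when NULL and `sim`
#'   is given, the generator's own reference is used
#' @param qc a [qc_params()]
#' @param n_hvg,n_pcs preprocessing sizes used for this run
#' @param k_neighbors,resolution clustering parameters
#' @param annotate_method correlation method for annotation
#' @param baseline_types types forming the T/B baseline
#' @param tag tag id to track (default the first simulated tag)
#' @param mixture_grouping "per_type" or "pooled"
#' @param seed run seed (recorded in every output)
#' @param outdir output directory
#' @return validated `RunConfig` list
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       reference_path = NULL, qc = qc_params(),
                       n_hvg = 500, n_pcs = 40,
                       k_neighbors = 20, resolution = 1,
                       annotate_method = "spearman",
                       baseline_types = c("Tcell", "Bcell"),
                       tag = NULL, mixture_grouping = "per_type",
                       seed = 1L, outdir = tempfile("atrace_run_")) {
  if (is.null(sim) && is.null(input_dir))
    stop("config error: either a simulation config or an input directory is required")
  if (!is.null(input_dir)) {
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv"))
      if (!file.exists(file.path(input_dir, f)))
        stop("config error: missing ", f, " in ", input_dir)
  }
  if (!is.null(reference_path) && !file.exists(reference_path))
    stop("config error: reference path does not exist: ", reference_path)
  if (is.null(reference_path) && is.null(sim))
    stop("config error: a reference is required when no simulation config is given")
  if (is.null(tag) && !is.null(sim)) tag <- sim$tag_ids[1]
  if (is.null(tag)) stop("config error: tag id required")
  structure(list(
    sim = sim, input_dir = input_dir, reference_path = reference_path,
    qc = qc, n_hvg = n_hvg, n_pcs = n_pcs,
    k_neighbors = k_neighbors, resolution = resolution,
    annotate_method = annotate_method,
    baseline_types = baseline_types, tag = tag,
    mixture_grouping = mixture_grouping,
    seed = as.integer(seed), outdir = outdir
  ), class = "RunConfig")
}

stamp_and_write <- function(table, path, seed) {
  # every output records the run seed in a header comment line
  con <- file(path, "w")
  writeLines(sprintf("# seed=%d", seed), con)
  close(con)
  tmp <- tempfile()
  write_result_table(table, tmp)
  file.append(path, tmp)
  unlink(tmp)
  invisible(path)
}

read_stamped_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full antigen-tracking pipeline
#'
#' Executes simulate (or load) -> QC -> normalize/PCA -> cluster/annotate ->
#' relative antigen signal -> mixture classification -> marker detection,
#' writing every intermediate table under `config$outdir` and returning a
#' manifest (stage, outputs, md5 hashes, wall time). Re-running with an
#' identical config and seed reproduces identical table contents.
#'
#' @param config a [run_config()]
#' @return data.frame manifest of class `RunManifest`, with the output
#'   directory in `attr(, "outdir")`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, paths, t0) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage,
      outputs = paste(basename(paths), collapse = ","),
      md5 = paste(unname(tools::md5sum(paths)), collapse = ","),
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      stringsAsFactors = FALSE
    )
  }
  out <- function(f) file.path(config$outdir, f)
  seed <- config$seed

  # 1. simulate or load
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$input_dir)) {
    bundle <- read_triplet_matrix(file.path(config$input_dir, "matrix.mtx"),
                                  file.path(config$input_dir, "features.tsv"),
                                  file.path(config$input_dir, "barcodes.tsv"))
    truth <- NULL
  } else {
    simcfg <- config$sim
    simcfg$seed <- seed
    sim <- simulate_counts(simcfg)
    bundle <- sim$bundle
    truth <- sim$truth
    stamp_and_write(truth$cells, out("truth_cells.tsv"), seed)
  }
  write_triplet_matrix(bundle, config$outdir)
  note("simulate", c(out("matrix.mtx"),
                     if (!is.null(truth)) out("truth_cells.tsv")), t0)

  # 2. QC
  t0 <- as.numeric(Sys.time())
  qcres <- qc_filter(bundle, config$qc)
  bundle <- qcres$bundle
  stamp_and_write(qcres$report, out("qc_report.tsv"), seed)
  message("QC: ", sum(qcres$report$pass), "/", nrow(qcres$report),
          " cells retained")
  note("qc", out("qc_report.tsv"), t0)

  # 3. normalize, HVG, PCA
  t0 <- as.numeric(Sys.time())
  norm <- lognormalize(bundle, config$qc)
  norm <- select_hvg(norm, n_hvg = min(config$n_hvg, nrow(bundle$gene_counts)))
  norm <- run_pca(norm, n_pcs = config$n_pcs)
  stamp_and_write(data.frame(gene = norm$hvg_ids), out("hvg.tsv"), seed)
  pcs <- data.frame(cell_id = rownames(norm$pca_scores), norm$pca_scores,
                    check.names = FALSE)
  stamp_and_write(pcs, out("pca_scores.tsv"), seed)
  note("norm_pca", c(out("hvg.tsv"), out("pca_scores.tsv")), t0)

  # 4. cluster + annotate
  t0 <- as.numeric(Sys.time())
  clusters <- cluster_cells(norm$pca_scores, k_neighbors = config$k_neighbors,
                            resolution = config$resolution, seed = seed)
  ref <- if (!is.null(config$reference_path))
    read_reference_profiles(config$reference_path)
  else make_reference(config$sim, scale_factor = config$qc$scale_factor)
  ann <- annotate_clusters(norm, clusters, ref,
                           method = config$annotate_method)
  stamp_and_write(ann$table, out("annotation.tsv"), seed)
  cell_ann <- data.frame(cell_id = names(clusters$labels),
                         cluster = unname(clusters$labels),
                         cell_type = unname(ann$cell_types),
                         stringsAsFactors = FALSE)
  stamp_and_write(cell_ann, out("cell_annotation.tsv"), seed)
  message("clustering: ", length(unique(clusters$labels)),
          " clusters over ", length(clusters$labels), " cells")
  note("cluster_annotate", c(out("annotation.tsv"),
                             out("cell_annotation.tsv")), t0)

  # 5. relative antigen signal + group comparisons
  t0 <- as.numeric(Sys.time())
  signal <- relative_signal(bundle, config$tag, config$baseline_types,
                            ann$cell_types)
  stamp_and_write(signal, out("antigen_signal.tsv"), seed)
  comp <- compare_types(signal, mode = "pairwise")
  stamp_and_write(comp, out("group_comparisons.tsv"), seed)
  note("antigen_signal", c(out("antigen_signal.tsv"),
                           out("group_comparisons.tsv")), t0)

  # 6. mixture classification
  t0 <- as.numeric(Sys.time())
  nonbase <- signal[!signal$cell_type %in% config$baseline_types, ]
  cls <- withCallingHandlers(
    classify_antigen(nonbase, grouping = config$mixture_grouping,
                     seed = seed),
    warning = function(w) {
      message("classify: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  fit_tab <- do.call(rbind, lapply(names(cls$fits), function(g) {
    f <- cls$fits[[g]]
    data.frame(group = g, pi1 = f$pi[1], pi2 = f$pi[2],
               mu1 = f$mu[1], mu2 = f$mu[2], sd1 = f$sd[1], sd2 = f$sd[2],
               mean_low = f$class_means["low"],
               mean_high = f$class_means["high"],
               loglik = f$loglik, n_iter = f$n_iter,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  if (is.null(fit_tab))
    fit_tab <- data.frame(group = character(0))
  stamp_and_write(fit_tab, out("mixture_fits.tsv"), seed)
  stamp_and_write(cls$labels, out("antigen_classes.tsv"), seed)
  note("classify", c(out("mixture_fits.tsv"), out("antigen_classes.tsv")), t0)

  # 7. markers of antigen-high cells, per classified group
  t0 <- as.numeric(Sys.time())
  marker_paths <- character(0)
  for (g in names(cls$fits)) {
    lab <- cls$labels[cls$labels$group == g, ]
    if (length(unique(stats::na.omit(lab$antigen_class))) < 2) next
    if (min(table(lab$antigen_class)) < 2) next
    sub <- subset_bundle(bundle, bundle_cells(bundle) %in% lab$cell_id)
    subnorm <- lognormalize(sub, config$qc)
    mk <- find_markers(subnorm,
                       stats::setNames(lab$antigen_class, lab$cell_id))
    p <- out(sprintf("markers_%s.tsv", gsub("[^A-Za-z0-9_-]", "_", g)))
    stamp_and_write(mk, p, seed)
    marker_paths <- c(marker_paths, p)
  }
  if (!length(marker_paths)) {
    p <- out("markers_none.tsv")
    stamp_and_write(data.frame(gene = character(0)), p, seed)
    marker_paths <- p
  }
  note("markers", marker_paths, t0)

  mf <- do.call(rbind, manifest)
  class(mf) <- c("RunManifest", "data.frame")
  attr(mf, "outdir") <- config$outdir
  attr(mf, "config") <- config
  mf
}

#' Summarize a pipeline run per cell type
#'
#' Joins annotation, median relative antigen signal, antigen-high fraction
#' and marker counts into one row per annotated cell type.
#'
#' @param manifest a [run_pipeline()] manifest
#' @return data.frame: cell_type, n_cells, median_relative_signal,
#'   frac_antigen_high (NA for types skipped by the mixture size floor),
#'   n_markers (passing genes; NA where no marker table exists)
#' @export
report_summary <- function(manifest) {
  stopifnot(inherits(manifest, "RunManifest"))
  required <- c("simulate", "qc", "norm_pca", "cluster_annotate",
                "antigen_signal", "classify", "markers")
  if (!all(required %in% manifest$stage))
    stop("incomplete manifest: missing stage(s) ",
         paste(setdiff(required, manifest$stage), collapse = ", "))
  outdir <- attr(manifest, "outdir")
  signal <- read_stamped_table(file.path(outdir, "antigen_signal.tsv"))
  classes <- read_stamped_table(file.path(outdir, "antigen_classes.tsv"))
  types <- sort(unique(signal$cell_type))
  rows <- lapply(types, function(ty) {
    sig <- signal[signal$cell_type == ty, ]
    cl <- classes[classes$group == ty, ]
    frac_high <- if (nrow(cl) && any(!is.na(cl$antigen_class)))
      mean(cl$antigen_class == "high", na.rm = TRUE) else NA_real_
    mpath <- file.path(outdir, sprintf("markers_%s.tsv",
                                       gsub("[^A-Za-z0-9_-]", "_", ty)))
    n_mark <- if (file.exists(mpath)) {
      mk <- read_stamped_table(mpath)
      if ("pass" %in% names(mk)) sum(mk$pass %in% c(TRUE, "TRUE")) else 0L
    } else NA_integer_
    data.frame(cell_type = ty, n_cells = nrow(sig),
               median_relative_signal = stats::median(sig$relative_signal),
               frac_antigen_high = frac_high, n_markers = n_mark,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
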