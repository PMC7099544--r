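#' Configuration for the end-to-end filter comparison
#'
#' @param input path to an image file, a numeric matrix, or a
#'   [synth_spec()].
#' @param filters subset of `c("icf", "traditional", "pso")` (at least one).
#' @param output_dir writable output directory (created if absent).
#' @param evaluation_point intra-pixel `(x, y)` for the ICF polynomials.
#' @param ein_fidelity `"canonical"` or `"printed"` e-term fidelity.
#' @param neighbor_mode `"nearest"` or `"bilinear"` diagonal sampling.
#' @param degenerate_tol `NULL` for the automatic tolerance.
#' @param prevalence_factor Table-of-behaviour prevalence factor.
#' @param kernel traditional HPF kernel matrix.
#' @param pso a [pso_config()].
#' @param n_bins histogram bins for the distribution summaries.
#' @param seed master seed (overrides `pso$seed` so one seed fixes a run).
#' @param verbose print stage progress.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(input, filters = c("icf", "traditional"),
                       output_dir = tempfile("icfhpf_run_"),
                       evaluation_point = c(1, 1),
                       ein_fidelity = "canonical",
                       neighbor_mode = "nearest",
                       degenerate_tol = NULL,
                       prevalence_factor = 10,
                       kernel = hpf_kernel(),
                       pso = pso_config(),
                       n_bins = 256L,
                       seed = 1L,
                       verbose = FALSE) {
  if (length(filters) == 0L)
    stop("at least one filter must be selected", call. = FALSE)
  filters <- match.arg(filters, c("icf", "traditional", "pso"),
                       several.ok = TRUE)
  stopifnot(length(evaluation_point) == 2L, is.finite(evaluation_point))
  pso$seed <- as.integer(seed)
  structure(list(input = input, filters = filters, output_dir = output_dir,
                 evaluation_point = evaluation_point,
                 ein_fidelity = ein_fidelity, neighbor_mode = neighbor_mode,
                 degenerate_tol = degenerate_tol,
                 prevalence_factor = prevalence_factor,
                 kernel = kernel, pso = pso, n_bins = as.integer(n_bins),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full filter comparison pipeline
#'
#' For each selected filter the pipeline produces the filtered image, its
#' transfer-function image, and its k-space magnitude; then all pairwise
#' image-space and k-space difference maps, an inverse-Fourier
#' reconstruction through each filtered image, and a Gaussian histogram
#' summary of each filtered image and of its k-space magnitude. Every
#' artifact is written (float TIFF + text matrix for maps, 8-bit PNG
#' preview for the log-magnitude, CSV for summaries) and listed, with an
#' MD5 content hash, in a JSON manifest that also records the resolved
#' configuration. Deterministic given the seed.
#'
#' @param cfg a [run_config()].
#' @return list with the in-memory results (`image`, `filtered`, `tf`,
#'   `kspace`, `differences`, `reconstructions`, `summaries`) plus
#'   `manifest_path`.
#' @export
run_comparison <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("`cfg` must be a run_config()", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  image <- stage("input", {
    if (inherits(cfg$input, "synth_spec")) synth_image(cfg$input)
    else if (is.matrix(cfg$input)) assert_image(cfg$input, "input")
    else read_image(cfg$input)
  })
  ep <- cfg$evaluation_point

  artifacts <- character(0)
  emit <- function(map, name, preview = FALSE) {
    tp <- file.path(cfg$output_dir, paste0(name, ".tiff"))
    xp <- file.path(cfg$output_dir, paste0(name, ".txt"))
    write_image(map, tp, "tiff32")
    write_image(map, xp, "text")
    artifacts <<- c(artifacts, tp, xp)
    if (preview) {
      pp <- file.path(cfg$output_dir, paste0(name, ".png"))
      write_image(map, pp, "png8")
      artifacts <<- c(artifacts, pp)
    }
    invisible(NULL)
  }

  emit(image, "original", preview = TRUE)

  filtered <- list()
  tf <- list()
  say("filtering with: %s", paste(cfg$filters, collapse = ", "))
  if ("icf" %in% cfg$filters) {
    res <- stage("icf", icf_image(image, ep[1], ep[2], cfg$degenerate_tol,
                                  cfg$ein_fidelity, cfg$neighbor_mode))
    filtered$icf <- res$delta_e
    tf$icf <- res$tf
  }
  if ("traditional" %in% cfg$filters) {
    out <- stage("traditional", traditional_hpf(image, cfg$kernel))
    filtered$traditional <- out
    tf$traditional <- transfer_function_map(out, image, cfg$degenerate_tol)$tf
  }
  if ("pso" %in% cfg$filters) {
    target <- if ("traditional" %in% cfg$filters) filtered$traditional
              else traditional_hpf(image, cfg$kernel)
    out <- stage("pso", pso_hpf(image, target, cfg$pso))
    filtered$pso <- out$output
    tf$pso <- transfer_function_map(out$output, image, cfg$degenerate_tol)$tf
  }

  kspace <- lapply(filtered, kspace_magnitude)
  for (nm in names(filtered)) {
    emit(filtered[[nm]], paste0("filtered_", nm))
    emit(tf[[nm]], paste0("tf_", nm))
    emit(kspace[[nm]]$magnitude, paste0("kspace_", nm))
    pp <- file.path(cfg$output_dir, paste0("kspace_", nm, "_log.png"))
    write_image(kspace[[nm]]$log_magnitude, pp, "png8")
    artifacts <- c(artifacts, pp)
  }

  differences <- list()
  nms <- names(filtered)
  if (length(nms) > 1L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in seq((i + 1L), length(nms))) {
        key <- paste0(nms[i], "_vs_", nms[j])
        differences[[paste0("image_", key)]] <-
          difference_map(filtered[[nms[i]]], filtered[[nms[j]]])
        differences[[paste0("kspace_", key)]] <-
          difference_map(kspace[[nms[i]]]$magnitude, kspace[[nms[j]]]$magnitude)
      }
    }
    for (nm in names(differences)) emit(differences[[nm]], paste0("diff_", nm))
  }

  reconstructions <- lapply(filtered, kspace_reconstruct)
  for (nm in names(reconstructions))
    emit(reconstructions[[nm]], paste0("reconstruction_", nm))

  summaries <- list()
  for (nm in nms) {
    summaries[[paste0("filtered_", nm)]] <- summarize_image(filtered[[nm]], cfg$n_bins)
    summaries[[paste0("kspace_", nm)]] <-
      summarize_image(kspace[[nm]]$magnitude, cfg$n_bins)
  }
  for (nm in names(summaries)) {
    sp <- file.path(cfg$output_dir, paste0("summary_", nm, ".csv"))
    write_summary_csv(summaries[[nm]], sp)
    artifacts <- c(artifacts, sp)
  }

  resolved <- cfg
  resolved$input <- if (is.matrix(cfg$input)) "<matrix>" else
    if (inherits(cfg$input, "synth_spec")) unclass(cfg$input) else cfg$input
  resolved$kernel <- unclass(cfg$kernel)
  resolved$pso <- unclass(cfg$pso)
  manifest <- list(
    config = unclass(resolved),
    artifacts = data.frame(path = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           row.names = NULL))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  say("wrote %d artifacts to %s", length(artifacts), cfg$output_dir)

  list(image = image, filtered = filtered, tf = tf, kspace = kspace,
       differences = differences, reconstructions = reconstructions,
       summaries = summaries, manifest_path = manifest_path)
}
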