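#' Analyze one root cross-section image
#'
#' Runs the full pipeline on a normalized grayscale matrix: segmentation,
#' dilation, cell detection, lateral-root filtering, the initial root
#' boundary, the relaxed-threshold recovery pass, tissue classification
#' (plus the maize extension when `species = "maize"`).
#'
#' @param I grayscale matrix in \[0, 1\] (see [load_image()]), or a path
#'   to an image file.
#' @param p an [ra_params()] object.
#' @return A classified `ra_root` model.
#' @examples
#' \donttest{
#' synth <- generate_root(synthetic_spec("wheat", seed = 7))
#' model <- analyze_image(synth$image, ra_params("wheat"))
#' table(model$cells$tissue)
#' }
#' @export
analyze_image <- function(I, p = ra_params()) {
  if (is.character(I)) I <- load_image(I)
  model <- detect_root_model(I, p)
  model <- recover_missed_cells(I, p, model)
  classify_cells(model, p)
}

#' Batch driver: analyze a list of images and write their statistics
#'
#' Processes each image through [analyze_image()] and [write_stats()].
#' One image's failure does not abort the batch; the outcome of every
#' input is recorded in the returned manifest. Two runs with identical
#' inputs and parameters produce identical CSV output (the pipeline has
#' no random component).
#'
#' @param images character vector of image paths.
#' @param params an [ra_params()] object, or path to a parameter file.
#' @param outdir output directory; one summary/cells/cheesewheel CSV
#'   trio is written per image, named after the image file.
#' @return Invisibly, the run manifest: data frame with `image`,
#'   `status` (`"ok"`/`"failed"`), `reason`, `n_cells` and `seconds`.
#'   Written to `manifest.csv` in `outdir` as well.
#' @export
run_pipeline <- function(images, params, outdir) {
  if (length(images) == 0) stop("no input images given", call. = FALSE)
  if (is.character(params)) params <- load_params(params)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  rows <- lapply(images, function(path) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      model <- analyze_image(path, params)
      base <- tools::file_path_sans_ext(basename(path))
      write_stats(model, outdir, base)
      list(status = "ok", reason = "", n = nrow(model$cells))
    }, error = function(e) list(status = "failed",
                                reason = conditionMessage(e), n = NA_integer_))
    message(sprintf("[rootanat] %s: %s", basename(path), res$status))
    data.frame(image = path, status = res$status, reason = res$reason,
               n_cells = res$n,
               seconds = round(proc.time()[["elapsed"]] - t0, 2))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Tissue-overlay visualization of a classified model
#'
#' Returns (and optionally writes) an RGB overlay with the conventional
#' tissue colours: cortex blue, stele and endodermis red, metaxylem
#' yellow, protoxylem cyan, aerenchyma magenta, epidermis orange.
#'
#' @param model a classified `ra_root`.
#' @param path optional PNG output path.
#' @return An `height x width x 3` RGB array, invisibly when `path` is
#'   given.
#' @export
tissue_overlay <- function(model, path = NULL) {
  cols <- list(epidermis = c(1, 0.6, 0), cortex = c(0, 0, 1),
               stele = c(1, 0, 0), endodermis = c(0.8, 0, 0),
               metaxylem = c(1, 1, 0), protoxylem = c(0, 1, 1),
               aerenchyma = c(1, 0, 1))
  base <- model$image
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  for (i in seq_len(nrow(model$cells))) {
    ti <- model$cells$tissue[i]
    if (is.null(cols[[ti]])) next
    px <- which(model$labels == model$cells$id[i])
    npx <- length(base)
    for (ch in 1:3) rgb[px + (ch - 1) * npx] <- cols[[ti]][ch]
  }
  if (!is.null(path)) {
    EBImage::writeImage(EBImage::Image(rgb, colormode = "Color"), path)
    return(invisible(rgb))
  }
  rgb
}
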