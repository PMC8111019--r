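#' Pipeline run configuration
#'
#' Bundles every choice of an end-to-end run — data source, descriptor
#' configuration, backbone, evaluation mode, neighbour counts, folds and the
#' single master seed all randomness derives from — into one validated,
#' JSON-serializable object.
#'
#' @param data a [phantom_spec()], a [feature_sim_spec()], or a file path to
#'   a feature-store CSV.
#' @param config descriptor configuration 1, 2 or 3 (image data only).
#' @param backbone_name `"stub"` (the deterministic arithmetic backbone) —
#'   a frozen pretrained extractor can be plugged in programmatically via
#'   [run_pipeline()]'s `backbone` argument.
#' @param mode evaluation mode passed to [run_cv()].
#' @param k neighbour counts.
#' @param n_folds folds (default 10).
#' @param seed master seed.
#' @param encoder optional [encoder_spec()] for `"autothorax"` mode.
#' @param out optional output directory for artifacts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(data, config = 3L, backbone_name = "stub",
                       mode = c("raw", "autothorax", "pca"), k = 11L,
                       n_folds = 10L, seed = 1L, encoder = NULL,
                       out = NULL) {
  mode <- match.arg(mode)
  if (!(inherits(data, "phantom_spec") || inherits(data, "feature_sim_spec")
        || (is.character(data) && length(data) == 1L)))
    stop("data must be a phantom_spec, a feature_sim_spec or a file path",
         call. = FALSE)
  if (!config %in% 1:3) stop("config must be 1, 2 or 3", call. = FALSE)
  if (!is.null(encoder)) stopifnot(inherits(encoder, "encoder_spec"))
  structure(list(data = data, config = as.integer(config),
                 backbone_name = backbone_name, mode = mode,
                 k = as.integer(k), n_folds = as.integer(n_folds),
                 seed = as.integer(seed), encoder = encoder, out = out),
            class = "run_config")
}

.fail_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate/load -> view extraction and descriptor tagging (image
#' data) -> cross-validated search evaluation, and optionally writes the
#' report and the feature store under `config$out`. Identical
#' configurations (including the seed) produce identical reports. Stage
#' failures abort with the stage name.
#'
#' @param config a [run_config()].
#' @param backbone a [backbone()] used for image data; defaults to
#'   [stub_backbone()] sized to the phantom images.
#' @return the [run_cv()] `eval_report`.
#' @export
#' @examples
#' cfg <- run_config(feature_sim_spec(200, dim = 32, informative_dim = 8,
#'                                    separation = 5, seed = 3),
#'                   mode = "raw", k = 5, n_folds = 5, seed = 3)
#' run_pipeline(cfg)$summary
run_pipeline <- function(config, backbone = NULL) {
  stopifnot(inherits(config, "run_config"))
  store <- .fail_stage("data", {
    if (inherits(config$data, "feature_sim_spec"))
      generate_feature_clusters(config$data)
    else if (inherits(config$data, "phantom_spec")) {
      ph <- generate_phantoms(config$data)
      if (is.null(backbone)) {
        side <- config$data$image_side
        blk <- max(1L, side %/% 7L)
        if (side %% blk != 0) blk <- .largest_divisor(side, side %/% 4L)
        backbone <- stub_backbone(block = blk, input_side = side)
      }
      .fail_stage("extract",
                  tag_archive(ph, config$config, backbone,
                              side = backbone$input_side))
    } else {
      if (!file.exists(config$data))
        stop("store file not found: ", config$data, call. = FALSE)
      read_feature_store(config$data)
    }
  })
  report <- .fail_stage("evaluate",
                        run_cv(store, mode = config$mode, k = config$k,
                               n_folds = config$n_folds, seed = config$seed,
                               spec = config$encoder))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out, "report.json"),
                 config = config)
    write_feature_store(store, file.path(config$out, "store.csv"))
  }
  report
}

.largest_divisor <- function(n, at_most) {
  for (b in seq(min(at_most, n), 1L)) if (n %% b == 0L) return(b)
  1L
}

#' Read an image manifest CSV
#'
#' Expects columns `id`, `path` and `label` (0/1); extra columns are
#' preserved. Duplicate ids and empty manifests are errors naming the
#' offenders.
#'
#' @param path manifest CSV path.
#' @return a data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(m) == 0L) stop("manifest is empty", call. = FALSE)
  missing_cols <- setdiff(c("id", "path", "label"), names(m))
  if (length(missing_cols) > 0)
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$id))
    stop("duplicate manifest ids: ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "),
         call. = FALSE)
  m
}

#' Write phantoms as PNG files plus a manifest
#'
#' @param phantoms a [generate_phantoms()] result.
#' @param dir output directory (created if needed).
#' @return path of the written manifest CSV, invisibly.
#' @export
write_phantom_pngs <- function(phantoms, dir) {
  stopifnot(inherits(phantoms, "phantom_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- phantoms$manifest
  man$path <- file.path(dir, paste0(man$id, ".png"))
  for (i in seq_along(phantoms$images))
    png::writePNG(phantoms$images[[i]], man$path[i])
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(man, out, row.names = FALSE)
  invisible(out)
}

#' Load grayscale images listed in a manifest
#'
#' Reads PNG files; colour images are reduced to grayscale by channel
#' averaging.
#'
#' @param manifest a data.frame from [read_manifest()] (or the phantom
#'   manifest with a `path` column).
#' @return list with `images` (intensity matrices) and the manifest.
#' @export
load_images <- function(manifest) {
  stopifnot(is.data.frame(manifest), "path" %in% names(manifest))
  images <- lapply(manifest$path, function(p) {
    px <- png::readPNG(p)
    if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE],
                                           c(1, 2), mean)
    px
  })
  list(images = images, manifest = manifest)
}

#' Write an evaluation report to JSON
#'
#' The report embeds the package version and, when given, the full run
#' configuration, so any output file identifies exactly how it was
#' produced.
#'
#' @param report an `eval_report`.
#' @param path output JSON path.
#' @param config optional [run_config()] echoed into the file.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(
    tool = "cxrsearch",
    version = as.character(utils::packageVersion("cxrsearch")),
    mode = report$mode, k = report$k, n_folds = report$n_folds,
    seed = report$seed, n = report$n,
    summary = report$summary, per_fold = report$per_fold,
    confusion = lapply(report$confusion, function(m) as.data.frame(m)))
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$data <- if (is.character(cfg$data)) cfg$data
                else c(list(type = class(config$data)), unclass(cfg$data))
    cfg$encoder <- if (is.null(cfg$encoder)) NULL else unclass(cfg$encoder)
    payload$config <- cfg
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
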