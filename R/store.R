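#' Construct a feature store
#'
#' A feature store is the archive container of the pipeline: one descriptor
#' row per image together with its id and binary label, plus metadata on how
#' the descriptors were produced (configuration and backbone). All
#' downstream stages — encoder training, PCA, indexing, cross-validation —
#' operate on feature stores.
#'
#' @param features numeric matrix, one row per item; all entries finite.
#' @param ids character vector of unique item ids, length `nrow(features)`.
#' @param labels integer/numeric vector of 0/1 labels (NA allowed for
#'   unlabelled items), same length.
#' @param config descriptor configuration: 1, 2, 3, `"sim"` or `"code"`.
#' @param backbone name of the backbone (or transform) that produced the
#'   rows.
#' @param descriptor_length per-view descriptor length used at extraction
#'   time (informational; default `NA`).
#' @return an object of class `feature_store`.
#' @export
feature_store <- function(features, ids, labels, config = NA,
                          backbone = NA_character_,
                          descriptor_length = NA_integer_) {
  if (!is.matrix(features) || !is.numeric(features))
    stop("features must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(features)))
    stop("features contain non-finite values", call. = FALSE)
  ids <- as.character(ids)
  if (length(ids) != nrow(features) || length(labels) != nrow(features))
    stop("ids and labels must match the number of feature rows",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]),
                                  collapse = ", "), call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L) | is.na(labels)))
    stop("labels must be 0, 1 or NA", call. = FALSE)
  structure(list(features = features, ids = ids, labels = labels,
                 config = config, backbone = backbone,
                 descriptor_length = descriptor_length),
            class = "feature_store")
}

#' @export
print.feature_store <- function(x, ...) {
  cat(sprintf(
    "<feature_store> %d x %d (config %s, backbone %s), %d positive\n",
    nrow(x$features), ncol(x$features), as.character(x$config),
    as.character(x$backbone), sum(x$labels == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.feature_store <- function(x) dim(x$features)

#' Subset a feature store by row
#'
#' @param x a [feature_store()].
#' @param i row index vector.
#' @param ... unused.
#' @return a feature store with the selected rows, metadata preserved.
#' @export
`[.feature_store` <- function(x, i, ...) {
  feature_store(x$features[i, , drop = FALSE], x$ids[i], x$labels[i],
                config = x$config, backbone = x$backbone,
                descriptor_length = x$descriptor_length)
}

#' Write a feature store to CSV
#'
#' Plain-text persistence: a commented metadata header (`# key=value` lines
#' carrying config, backbone, descriptor length and package version)
#' followed by a CSV table with columns `id`, `label`, `f1..fd`.
#'
#' @param store a [feature_store()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_feature_store <- function(store, path) {
  stopifnot(inherits(store, "feature_store"))
  meta <- c(sprintf("# cxrsearch_version=%s",
                    as.character(utils::packageVersion("cxrsearch"))),
            sprintf("# config=%s", as.character(store$config)),
            sprintf("# backbone=%s", as.character(store$backbone)),
            sprintf("# descriptor_length=%s",
                    as.character(store$descriptor_length)))
  writeLines(meta, path)
  tab <- data.table::data.table(id = store$ids, label = store$labels)
  feat <- data.table::as.data.table(store$features)
  data.table::setnames(feat, sprintf("f%d", seq_len(ncol(store$features))))
  data.table::fwrite(cbind(tab, feat), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a feature store from CSV
#'
#' @param path file written by [write_feature_store()].
#' @return a [feature_store()].
#' @export
read_feature_store <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- data.table::fread(path, skip = length(hdr), header = TRUE)
  feat <- as.matrix(tab[, setdiff(names(tab), c("id", "label")),
                        with = FALSE])
  dimnames(feat) <- NULL
  cfg <- meta$config
  if (!is.null(cfg) && cfg %in% c("1", "2", "3")) cfg <- as.integer(cfg)
  feature_store(feat, ids = tab$id, labels = tab$label,
                config = if (is.null(cfg)) NA else cfg,
                backbone = if (is.null(meta$backbone)) NA_character_
                           else meta$backbone,
                descriptor_length =
                  if (is.null(meta$descriptor_length)) NA_integer_
                  else suppressWarnings(as.integer(meta$descriptor_length)))
}
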