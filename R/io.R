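#' Read and write the pipeline's tabular formats
#'
#' Plain-text CSV carriers for the pipeline's objects.  Suitability grids are
#' written in long format (`cell_id, species, suitability`, zero cells
#' omitted) with the full cell universe recorded in a `# universe:` header so
#' empty cells survive the round trip; occurrence sets as
#' (`species, cell_id`) rows; trait matrices as species x trait tables;
#' component tables with a provenance header (`# key: value` lines recording
#' eps, threshold, reps and seed).
#'
#' @param grid a [suitability_grid()].
#' @param path file path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name eva_io
NULL

#' @rdname eva_io
#' @export
write_grid_csv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# universe: ", paste(colnames(grid), collapse = ";")), con)
  long <- which(unclass(grid) > 0, arr.ind = TRUE)
  df <- data.frame(cell_id = colnames(grid)[long[, "col"]],
                   species = rownames(grid)[long[, "row"]],
                   suitability = grid[long])
  df <- df[order(df$species, df$cell_id), ]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname eva_io
#' @export
read_grid_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# universe: ")) {
    stop("grid CSV lacks the '# universe:' header", call. = FALSE)
  }
  cells <- strsplit(sub("^# universe: ", "", first), ";", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  species <- sort(unique(df$species))
  m <- matrix(0, length(species), length(cells),
              dimnames = list(species, cells))
  m[cbind(df$species, df$cell_id)] <- df$suitability
  suitability_grid(m)
}

#' @rdname eva_io
#' @param occ named list of occupied cell ids per species.
#' @export
write_occurrences_csv <- function(occ, path) {
  df <- data.frame(
    species = rep(names(occ), lengths(occ)),
    cell_id = unlist(occ, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname eva_io
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df$cell_id, df$species)
}

#' @rdname eva_io
#' @param traits species x traits matrix.
#' @export
write_traits_csv <- function(traits, path) {
  df <- data.frame(species = rownames(traits), as.data.frame(traits),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname eva_io
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "species"), drop = FALSE])
  rownames(m) <- df$species
  m
}

#' @rdname eva_io
#' @param components a clade component table (see [compute_components()]).
#' @export
write_components_csv <- function(components, path) {
  params <- attr(components, "params")
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(params)) {
    writeLines(sprintf("# %s: %s", key, params[[key]]), con)
  }
  utils::write.csv(as.data.frame(components), con, row.names = FALSE)
  invisible(path)
}

#' @rdname eva_io
#' @export
read_components_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!startsWith(lines, "# ")],
                        stringsAsFactors = FALSE)
  if (length(hdr)) {
    keys <- sub("^# ([^:]+):.*$", "\\1", hdr)
    vals <- sub("^# [^:]+: ?", "", hdr)
    attr(df, "params") <- stats::setNames(as.list(vals), keys)
  }
  df
}

#' Write a synthetic dataset to a directory
#'
#' Writes `tree.nwk`, `clade_tree.nwk`, `grid.csv`, `occurrences.csv`,
#' `traits.csv`, `components.csv` and a `truth.json` sidecar recording the
#' generating parameters and seed.
#'
#' @param dataset a [simulate_eva_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eva_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eva_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dated_tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_dated_tree(dataset$backbone, file.path(dir, "clade_tree.nwk"))
  write_grid_csv(dataset$grid, file.path(dir, "grid.csv"))
  write_occurrences_csv(dataset$occ, file.path(dir, "occurrences.csv"))
  write_traits_csv(dataset$traits, file.path(dir, "traits.csv"))
  comp <- dataset$components
  attr(comp, "params") <- list(
    seed = dataset$config$seed, cutoff = dataset$truth$cutoff,
    eps = dataset$config$eps, threshold = dataset$config$threshold,
    reps = dataset$config$reps
  )
  write_components_csv(comp, file.path(dir, "components.csv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
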