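# Canonical in-memory screen container: per-condition event tables (one
# column per marker well, isotype-control wells as ISO_<id> columns), the
# plate map, and the ordered condition list (untreated first).

new_screen <- function(events, plate_map, conditions, truth = NULL) {
  scr <- structure(
    list(events = events, plate_map = plate_map,
         conditions = conditions, truth = truth),
    class = "sasome_screen"
  )
  validate_screen(scr)
}

#' @export
print.sasome_screen <- function(x, ...) {
  cat("sasome_screen:", length(x$plate_map$marker), "markers x",
      length(x$conditions), "conditions (",
      paste(x$conditions, collapse = ", "), ")\n")
  cat("  events per well:", nrow(x$events[[1L]]), "| isotype groups:",
      paste(unique(x$plate_map$isotype_id), collapse = ", "), "\n")
  invisible(x)
}

# Validates structure and floors nonpositive intensities to 1e-3 of the
# per-well median of positive events (log-scale steps downstream need
# positivity); the number of floored events is reported.
validate_screen <- function(scr) {
  pm <- scr$plate_map
  if (!all(c("marker", "isotype_id") %in% names(pm))) {
    abort("plate map needs columns marker, isotype_id")
  }
  if (anyDuplicated(pm$marker)) abort("duplicated plate-map marker entries")
  markers <- pm$marker
  iso_cols <- paste0("ISO_", unique(pm$isotype_id))

  ref_cols <- colnames(scr$events[[1L]])
  floored <- 0L
  for (cond in scr$conditions) {
    ev <- scr$events[[cond]]
    if (is.null(ev) || nrow(ev) == 0L) abort("empty well table for condition ", cond)
    if (!identical(colnames(ev), ref_cols)) {
      asym <- union(setdiff(colnames(ev), ref_cols), setdiff(ref_cols, colnames(ev)))
      abort("marker columns differ between conditions; asymmetric: ",
            paste(asym, collapse = ", "))
    }
    for (cl in colnames(ev)) {
      v <- ev[[cl]]
      if (!is.numeric(v)) abort("non-numeric intensities in ", cond, "/", cl)
      if (any(!is.finite(v))) abort("non-finite intensities in ", cond, "/", cl)
      bad <- v <= 0
      if (any(bad)) {
        pos_med <- median(v[!bad])
        if (!is.finite(pos_med) || pos_med <= 0) {
          abort("well ", cond, "/", cl, " has no positive events")
        }
        ev[[cl]][bad] <- 1e-3 * pos_med
        floored <- floored + sum(bad)
      }
    }
    scr$events[[cond]] <- ev
  }
  if (floored > 0L) {
    message("floored ", floored, " nonpositive events to 1e-3 x well median")
  }

  missing_cols <- setdiff(markers, ref_cols)
  if (length(missing_cols)) {
    abort("markers in plate map but absent from event tables: ",
          paste(missing_cols, collapse = ", "))
  }
  unmapped <- setdiff(setdiff(ref_cols, iso_cols), markers)
  if (length(unmapped)) {
    abort("event columns missing a plate-map entry: ",
          paste(unmapped, collapse = ", "))
  }
  scr
}

#' Retrieve one event sample from a screen
#'
#' @param screen A `sasome_screen`.
#' @param marker Marker id (or an `ISO_<isotype id>` control-well id).
#' @param condition Condition id.
#' @return Numeric vector of per-event linear fluorescence intensities.
#' @export
event_sample <- function(screen, marker, condition) {
  ev <- screen$events[[condition]]
  if (is.null(ev)) abort("unknown condition: ", condition)
  if (!marker %in% colnames(ev)) abort("unknown marker well: ", marker)
  ev[[marker]]
}

#' Write a screen bundle to disk
#'
#' One tab-delimited event table per condition (`events_<condition>.tsv`,
#' columns = marker and `ISO_<id>` wells, rows = events), the plate map
#' (`plate_map.tsv`: marker, isotype_id, well) and the condition order
#' (`conditions.txt`).
#'
#' @param screen A `sasome_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in screen$conditions) {
    write.table(screen$events[[cond]],
                file.path(dir, paste0("events_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(screen$plate_map, file.path(dir, "plate_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(screen$conditions, file.path(dir, "conditions.txt"))
  invisible(dir)
}

#' Read and validate a surfaceome screen
#'
#' Assembles a validated screen from per-condition event tables and a plate
#' map. Checks that every marker is present in every condition, that every
#' event column has a plate-map entry (isotype wells are recognized by their
#' `ISO_<isotype id>` names), and that all intensities are finite; intensities
#' `<= 0` are floored to `1e-3` of the well median with a reported count.
#'
#' @param event_paths Named character vector of event-table paths; names are
#'   condition ids. The untreated condition must be named `"untreated"` or be
#'   listed first.
#' @param plate_map_path Path to the plate-map table.
#' @return A `sasome_screen`.
#' @export
read_screen <- function(event_paths, plate_map_path) {
  if (is.null(names(event_paths)) || any(names(event_paths) == "")) {
    abort("`event_paths` must be named by condition")
  }
  for (p in c(unname(event_paths), plate_map_path)) {
    if (!file.exists(p)) abort("file not found: ", p)
  }
  conditions <- names(event_paths)
  if ("untreated" %in% conditions) {
    conditions <- c("untreated", setdiff(conditions, "untreated"))
  }
  events <- lapply(event_paths, function(p) {
    read.delim(p, check.names = FALSE)
  })[conditions]
  plate_map <- read.delim(plate_map_path, check.names = FALSE,
                          colClasses = "character")
  new_screen(events, plate_map, conditions)
}

#' Read a screen bundle written by [write_screen()]
#'
#' @param dir Bundle directory.
#' @return A `sasome_screen`.
#' @export
read_screen_bundle <- function(dir) {
  if (!dir.exists(dir)) abort("screen bundle not found: ", dir)
  conds <- readLines(file.path(dir, "conditions.txt"))
  paths <- setNames(file.path(dir, paste0("events_", conds, ".tsv")), conds)
  read_screen(paths, file.path(dir, "plate_map.tsv"))
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT (set id, description, genes...). Duplicate
#' genes within a set are removed; set sizes count unique genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene ids per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(setNames(list(), character(0)))
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3L)) {
    abort("malformed GMT line(s) with < 3 fields at: ",
          paste(which(nf < 3L), collapse = ", "))
  }
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write a gene-set collection in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(s) {
    paste(c(s, "na", gene_sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat gene-to-GO-term annotation table
#'
#' Tab-delimited with columns `gene` and `go_term`; one row per annotation.
#' No ontology traversal is performed — pre-expand the ontology if needed.
#'
#' @param path Table path.
#' @return data.frame with columns gene, go_term.
#' @export
read_go_table <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  go <- read.delim(path, colClasses = "character")
  if (!all(c("gene", "go_term") %in% names(go))) {
    abort("GO table needs columns gene, go_term")
  }
  go
}
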