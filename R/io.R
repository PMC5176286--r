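#' Load a stack of connectivity matrices from a directory
#'
#' Reads every regular file in `path` (lexicographic filename order defines
#' subject order) as a whitespace- or comma-delimited square numeric matrix.
#' This is the layout used by per-subject connectivity text files such as the
#' USC Multimodal Connectivity Database exports.
#'
#' @param path directory containing one delimited D x D matrix per file.
#' @param symmetrize `"average"` (default) or `"strict"`, see
#'   [as_connectivity_stack()].
#' @param skip_corrupt if `TRUE`, files that fail to parse as a square
#'   numeric matrix are skipped with a message reporting the filename and the
#'   total count; if `FALSE` (default) they raise an error.
#' @param pattern optional regular expression filtering filenames.
#' @return a `connectivity_stack`; subject ids are the file names without
#'   extension.
#' @export
load_stack <- function(path, symmetrize = c("average", "strict"),
                       skip_corrupt = FALSE, pattern = NULL) {
  symmetrize <- match.arg(symmetrize)
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  files <- files[!dir.exists(files)]
  files <- files[!grepl("\\.json$", files)]
  if (length(files) < 2) stop("need at least 2 matrix files in ", path,
                              call. = FALSE)
  mats <- list()
  ids <- character()
  skipped <- 0L
  for (f in files) {
    X <- tryCatch(read_matrix_file(f), error = function(e) e)
    if (inherits(X, "error")) {
      if (skip_corrupt) {
        message("skipping unreadable file: ", basename(f),
                " (", conditionMessage(X), ")")
        skipped <- skipped + 1L
        next
      }
      stop("failed to read ", basename(f), ": ", conditionMessage(X),
           call. = FALSE)
    }
    mats[[length(mats) + 1L]] <- X
    ids <- c(ids, sub("\\.[^.]*$", "", basename(f)))
  }
  if (skipped > 0) message(sprintf("skipped %d corrupt file(s)", skipped))
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    bad <- ids[dims != stats::median(dims)]
    stop("dimension mismatch across files (e.g. ",
         paste(utils::head(bad, 3), collapse = ", "), ")", call. = FALSE)
  }
  node_labels <- NULL
  meta_file <- file.path(path, "stack_meta.json")
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    if (length(meta$subject_ids) == length(ids)) ids <- meta$subject_ids
    if (length(meta$node_labels) == nrow(mats[[1]])) {
      node_labels <- meta$node_labels
    }
  }
  tryCatch(
    as_connectivity_stack(mats, node_labels = node_labels,
                          subject_ids = ids, symmetrize = symmetrize),
    error = function(e) {
      # re-raise symmetry/validation errors naming the offending file
      m <- regmatches(conditionMessage(e),
                      regexpr("matrix [0-9]+", conditionMessage(e)))
      if (length(m) == 1) {
        n <- as.integer(sub("matrix ", "", m))
        stop(sub(m, paste0("file '", ids[n], "'"), conditionMessage(e)),
             call. = FALSE)
      }
      stop(e)
    })
}

read_matrix_file <- function(f) {
  X <- as.matrix(utils::read.table(f, header = FALSE,
                                   sep = "", comment.char = "",
                                   colClasses = "character"))
  # comma-delimited fallback: single column containing commas
  if (ncol(X) == 1 && any(grepl(",", X))) {
    X <- as.matrix(utils::read.table(f, header = FALSE, sep = ",",
                                     colClasses = "character"))
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("non-numeric entries")
  if (nrow(X) != ncol(X)) stop(sprintf("non-square (%d x %d)",
                                       nrow(X), ncol(X)))
  unname(X)
}

#' Write a connectivity stack to a directory of text matrices
#'
#' Serializes each matrix as a whitespace-delimited text file (17 significant
#' digits, so values round-trip through [load_stack()]) plus a
#' `stack_meta.json` sidecar with node labels, subject order and, for a
#' centered stack, the mean matrix.
#'
#' @param stack a `connectivity_stack` or `centered_stack`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  N <- n_subjects(stack)
  width <- max(5L, nchar(as.character(N)))
  for (n in seq_len(N)) {
    X <- unvec(stack$data[n, ], stack$D)
    f <- file.path(path, sprintf("%0*d_%s.txt", width, n,
                                 gsub("[^A-Za-z0-9_.-]", "_",
                                      stack$subject_ids[n])))
    utils::write.table(format(X, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       f, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  meta <- list(node_labels = stack$node_labels,
               subject_ids = stack$subject_ids,
               centered = inherits(stack, "centered_stack"))
  if (!is.null(stack$mean)) meta$mean <- unname(stack$mean)
  jsonlite::write_json(meta, file.path(path, "stack_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a node coordinate table
#'
#' Reads a tab-separated table with header `node_id`, `x`, `y`, `z`
#' (coordinates in mm), as used for spatial export of module weights.
#'
#' @param path TSV file path.
#' @return a tibble with columns `node_id` (character), `x`, `y`, `z`.
#' @export
read_roi_coordinates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("coordinate table must have columns node_id, x, y, z",
         call. = FALSE)
  }
  tab <- tab[, need]
  tab$node_id <- as.character(tab$node_id)
  if (anyDuplicated(tab$node_id)) stop("duplicate node_id entries",
                                       call. = FALSE)
  if (!all(is.finite(as.matrix(tab[, c("x", "y", "z")])))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  tibble::as_tibble(tab)
}
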