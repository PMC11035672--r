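## Binary masks and annotation manifests.
##
## A mask is a logical matrix in row-major raster convention: element
## [r, c] is pixel (row r, col c), 0-based in the coordinate API, origin at
## the top-left. An all-FALSE mask is the "no finding" annotation, meaning
## the target structure is absent from the frame.

#' Construct a binary mask
#'
#' @param x a logical (or coercible numeric 0/1) matrix; rows are image rows.
#' @return a `binary_mask` object (a classed logical matrix).
#' @examples
#' m <- binary_mask(matrix(FALSE, 4, 4))
#' is_no_finding(m)
#' @export
binary_mask <- function(x) {
  if (!is.matrix(x)) stop("binary_mask: `x` must be a matrix", call. = FALSE)
  storage.mode(x) <- "logical"
  if (anyNA(x)) stop("binary_mask: NA pixels are not allowed", call. = FALSE)
  structure(x, class = "binary_mask")
}

#' Construct a mask from 0-based (row, col) foreground coordinates
#'
#' @param height,width frame dimensions in pixels.
#' @param coords two-column matrix (or data.frame) of 0-based (row, col)
#'   pairs; may have zero rows for a "no finding" mask.
#' @export
mask_from_coords <- function(height, width, coords = NULL) {
  m <- matrix(FALSE, nrow = height, ncol = width)
  if (!is.null(coords) && NROW(coords) > 0) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 2) stop("coords must have two columns (row, col)", call. = FALSE)
    if (any(coords[, 1] < 0 | coords[, 1] >= height |
            coords[, 2] < 0 | coords[, 2] >= width))
      stop("coords out of bounds for ", height, "x", width, " frame", call. = FALSE)
    m[cbind(coords[, 1] + 1L, coords[, 2] + 1L)] <- TRUE
  }
  binary_mask(m)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d foreground px%s>\n",
              nrow(x), ncol(x), sum(x),
              if (!any(x)) " (no finding)" else ""))
  invisible(x)
}

#' Foreground coordinates of a mask
#'
#' @param mask a `binary_mask`.
#' @return integer matrix of 0-based (row, col) pairs, one per foreground px.
#' @export
mask_coords <- function(mask) {
  idx <- which(unclass(mask), arr.ind = TRUE)
  out <- cbind(idx[, 1] - 1L, idx[, 2] - 1L)
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

#' Is a mask the "no finding" (empty) annotation?
#' @param mask a `binary_mask` or logical matrix.
#' @export
is_no_finding <- function(mask) !any(mask)

# internal: coerce to plain logical matrix, validating type
as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) return(unclass(mask))
  if (is.matrix(mask) && (is.logical(mask) || is.numeric(mask)))
    return(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  stop("expected a binary_mask or logical matrix", call. = FALSE)
}

# internal: masks are comparable only on identical dimensions
check_same_dim <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop(sprintf("masks are not comparable: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(TRUE)
}

#' Read a binary mask from a single-channel 8-bit PNG
#'
#' Pixels with value >= 128 (of 255) become foreground. Masks written by
#' [write_mask()] use 0/255, so the midpoint threshold is robust.
#'
#' @param path PNG file path.
#' @return a `binary_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path, call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("unreadable PNG '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) {
      img <- img[, , 1]
    } else {
      stop("mask must be single-channel; '", path, "' has ",
           dim(img)[3], " channels", call. = FALSE)
    }
  }
  # readPNG scales to [0,1]; recover the 8-bit level before thresholding
  binary_mask(round(img * 255) >= 128)
}

#' Write a binary mask as a single-channel 8-bit PNG (0 background / 255
#' foreground)
#'
#' @param mask a `binary_mask`.
#' @param path destination path; the parent directory must exist.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  if (!dir.exists(dirname(path)))
    stop("cannot write mask: no such directory: ", dirname(path), call. = FALSE)
  png::writePNG(m * 1.0, target = path)
  invisible(path)
}

manifest_cols <- c("annotator_id", "frame_id", "structure", "role", "mask_path")
ref_cols <- c("frame_id", "structure", "expert_id", "mask_path")
annotation_roles <- c("ordinary", "training_gold", "running_gold")

#' Load a campaign annotation manifest
#'
#' The manifest is a UTF-8 CSV with header columns
#' `annotator_id,frame_id,structure,role,mask_path` (optionally `elapsed_s`);
#' `mask_path` is resolved relative to the manifest location. Each row is
#' read into an annotation record with its mask.
#'
#' @param path manifest CSV path.
#' @param load_masks read the mask rasters (default TRUE); with FALSE only
#'   the table is validated and returned with `mask = NULL` per record.
#' @return a list of annotation records (class `annotation`): fields
#'   `annotator_id`, `frame_id`, `structure`, `role`, `mask`, `elapsed_s`.
#' @export
load_manifest <- function(path, load_masks = TRUE) {
  df <- read_manifest_table(path, manifest_cols)
  if (nrow(df) == 0) return(list())
  bad_role <- setdiff(unique(df$role), annotation_roles)
  if (length(bad_role))
    stop("manifest '", path, "': unknown role(s): ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  key <- paste(df$annotator_id, df$frame_id, df$structure, sep = "\x1f")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("manifest '", path, "': duplicate (annotator_id, frame_id, structure): ",
         paste(sprintf("(%s, %s, %s)", dup$annotator_id, dup$frame_id, dup$structure),
               collapse = "; "), call. = FALSE)
  }
  paths <- resolve_paths(df$mask_path, dirname(path))
  check_paths_exist(paths, path)
  lapply(seq_len(nrow(df)), function(i) {
    annotation(annotator_id = df$annotator_id[i],
               frame_id = df$frame_id[i],
               structure = df$structure[i],
               role = df$role[i],
               mask = if (load_masks) read_mask(paths[i]) else NULL,
               elapsed_s = if ("elapsed_s" %in% names(df)) df$elapsed_s[i] else NA_real_)
  })
}

#' Load expert reference masks
#'
#' Parallel CSV to the manifest: `frame_id,structure,expert_id,mask_path`.
#' At most one reference per (frame_id, structure, expert_id).
#'
#' @param path reference CSV path.
#' @param load_masks read mask rasters (default TRUE).
#' @return list of `expert_reference` records.
#' @export
load_expert_refs <- function(path, load_masks = TRUE) {
  df <- read_manifest_table(path, ref_cols)
  if (nrow(df) == 0) return(list())
  key <- paste(df$frame_id, df$structure, df$expert_id, sep = "\x1f")
  if (anyDuplicated(key))
    stop("reference table '", path,
         "': duplicate (frame_id, structure, expert_id) rows", call. = FALSE)
  paths <- resolve_paths(df$mask_path, dirname(path))
  check_paths_exist(paths, path)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(frame_id = df$frame_id[i], structure = df$structure[i],
                   expert_id = df$expert_id[i],
                   mask = if (load_masks) read_mask(paths[i]) else NULL),
              class = "expert_reference")
  })
}

#' Construct an annotation record
#'
#' @param annotator_id,frame_id,structure identifiers.
#' @param mask a `binary_mask` (or NULL when deferred).
#' @param role one of `ordinary`, `training_gold`, `running_gold`.
#' @param elapsed_s optional annotation time in seconds.
#' @export
annotation <- function(annotator_id, frame_id, structure, mask,
                       role = "ordinary", elapsed_s = NA_real_) {
  role <- match.arg(role, annotation_roles)
  if (!is.null(mask) && !inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  # `structure` is a field name here, so call the base constructor explicitly
  base::structure(list(annotator_id = as.character(annotator_id),
                       frame_id = as.character(frame_id),
                       structure = as.character(structure),
                       role = role, mask = mask, elapsed_s = elapsed_s),
                  class = "annotation")
}

read_manifest_table <- function(path, required) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if ("elapsed_s" %in% names(df)) df$elapsed_s <- as.numeric(df$elapsed_s)
  df
}

resolve_paths <- function(paths, base) {
  ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
}

check_paths_exist <- function(paths, manifest) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("manifest '", manifest, "': missing mask file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
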