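#' Construct a rating matrix
#'
#' A rating matrix holds the integer scores given by `r` experts to `n`
#' survey items on a bounded ordinal scale `1..scale_max`.  Rows are experts,
#' columns are items — the same orientation as the CSV dialect read by
#' [read_ratings_csv()].
#'
#' @param x numeric matrix (or object coercible to one) of integer scores;
#'   rows are experts, columns are items.
#' @param scale_max upper end of the rating scale (default 10, i.e. a 1-10
#'   Likert-type scale).
#' @return an integer matrix of class `"rating_matrix"` with attribute
#'   `scale_max`.
#' @examples
#' m <- rating_matrix(cbind(c(5, 5, 7)))   # 3 experts, 1 item
#' index_pwa(m)$per_item                    # 1/3
#' @export
rating_matrix <- function(x, scale_max = 10L) {
  x <- as.matrix(x)
  scale_max <- as.integer(scale_max)
  if (length(scale_max) != 1L || is.na(scale_max) || scale_max < 2L)
    stop("`scale_max` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(x))
    stop("ratings must be numeric", call. = FALSE)
  if (anyNA(x))
    stop("ratings must not contain missing values", call. = FALSE)
  if (any(x != round(x)))
    stop("ratings must be integers", call. = FALSE)
  storage.mode(x) <- "integer"
  if (any(x < 1L | x > scale_max))
    stop(sprintf("ratings must lie in [1, %d]", scale_max), call. = FALSE)
  if (nrow(x) < 2L)
    stop("a rating matrix needs at least 2 experts (pairwise indices divide by r(r-1))",
         call. = FALSE)
  if (ncol(x) < 1L)
    stop("a rating matrix needs at least 1 item", call. = FALSE)
  structure(x, scale_max = scale_max, class = c("rating_matrix", class(x)))
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d experts x %d items, scale 1-%d\n",
              nrow(x), ncol(x), attr(x, "scale_max")))
  print(unclass(x))
  invisible(x)
}

# Accept either a rating_matrix or a plain matrix plus scale_max.
as_rating_matrix <- function(x, scale_max = NULL) {
  if (inherits(x, "rating_matrix") && is.null(scale_max)) return(x)
  rating_matrix(x, scale_max = if (is.null(scale_max)) 10L else scale_max)
}

scale_of <- function(m) as.integer(attr(m, "scale_max"))

#' Built-in small rating matrices used in examples and tests
#'
#' A registry of deterministic fixtures, each a single-item
#' [rating_matrix()] on the default 1-10 scale:
#' \describe{
#'   \item{`"bimodal-9v3"`}{9 experts scoring (1,1,2,9,9,10,10,10,5): a
#'     5-vs-3 split into a high and a low opinion cluster plus one
#'     unaffiliated expert.}
#'   \item{`"unanimous-4"`}{5 experts all scoring 4.}
#'   \item{`"uniform-spread"`}{10 experts, one per scale point 1..10.}
#'   \item{`"tied-modes"`}{4 experts scoring (5,5,7,7): two tied modal
#'     scores.}
#' }
#'
#' @param name fixture name (see above).
#' @return a [rating_matrix()].
#' @examples
#' make_fixture("bimodal-9v3")
#' @export
make_fixture <- function(name) {
  reg <- list(
    "bimodal-9v3"    = c(1L, 1L, 2L, 9L, 9L, 10L, 10L, 10L, 5L),
    "unanimous-4"    = rep(4L, 5L),
    "uniform-spread" = 1:10,
    "tied-modes"     = c(5L, 5L, 7L, 7L)
  )
  if (!name %in% names(reg))
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(names(reg), collapse = ", ")), call. = FALSE)
  rating_matrix(cbind(reg[[name]]), scale_max = 10L)
}

#' Read a ratings CSV
#'
#' Reads an experts-by-items matrix of integer scores.  Rows are experts and
#' columns are items; an optional header row of column labels is detected
#' automatically (any non-numeric field in the first row).  Malformed cells
#' raise an error naming the offending row and column.
#'
#' @param path path to a comma-separated file.
#' @param scale_max rating-scale upper end (default 10).
#' @return a [rating_matrix()].
#' @seealso [write_ratings_csv()]
#' @export
read_ratings_csv <- function(path, scale_max = 10L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ratings file: ", path, call. = FALSE)
  cells <- lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop("ragged CSV: rows have differing numbers of fields", call. = FALSE)
  first_num <- suppressWarnings(as.numeric(cells[[1L]]))
  header <- NULL
  if (anyNA(first_num)) {
    header <- cells[[1L]]
    cells <- cells[-1L]
    if (length(cells) == 0L) stop("ratings file has a header but no data rows", call. = FALSE)
  }
  nr <- length(cells)
  nc <- ncols[[1L]]
  m <- matrix(NA_integer_, nrow = nr, ncol = nc)
  for (i in seq_len(nr)) {
    vals <- suppressWarnings(as.numeric(cells[[i]]))
    bad <- which(is.na(vals) | vals != round(vals) | vals < 1 | vals > scale_max)
    if (length(bad) > 0L)
      stop(sprintf(
        "invalid rating '%s' at data row %d, column %d (expected integer in [1, %d])",
        cells[[i]][bad[1L]], i, bad[1L], scale_max), call. = FALSE)
    m[i, ] <- as.integer(vals)
  }
  if (!is.null(header)) colnames(m) <- header
  rating_matrix(m, scale_max = scale_max)
}

#' Write a ratings CSV
#'
#' @param m a [rating_matrix()] (or plain integer matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = ",", row.names = FALSE,
                     col.names = !is.null(colnames(m)), quote = FALSE)
  invisible(path)
}
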