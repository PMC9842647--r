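# Internal helpers shared across modules.

# Scalar validators ---------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x))
  }
  as.numeric(x)
}

check_matrix <- function(x, name = "matrix") {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  x
}

# Require named dimnames on a cells x genes matrix.
check_cells_genes <- function(x, name = "matrix") {
  x <- check_matrix(x, name)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry cell rownames and gene colnames.", name))
  }
  x
}

# Symmetric moving-average smoothing matrix (genes x genes), window truncated
# at the ends: column j averages rows max(1, j-h) .. min(n, j+h).
moving_average_operator <- function(n, window) {
  h <- (window - 1L) %/% 2L
  idx <- lapply(seq_len(n), function(j) {
    seq.int(max(1L, j - h), min(n, j + h))
  })
  j_all <- rep.int(seq_len(n), lengths(idx))
  i_all <- unlist(idx, use.names = FALSE)
  w <- rep.int(1 / lengths(idx), lengths(idx))
  Matrix::sparseMatrix(i = i_all, j = j_all, x = w, dims = c(n, n))
}

# Pearson r that returns 0 (not NA) when either vector is constant.
safe_pearson <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

sorted_chroms <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}
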