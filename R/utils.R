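`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Keeps all randomness funnelled through one user-visible seed while giving
#' each pipeline stage an independent stream. Result is a positive integer
#' below 2^31.
#'
#' @param seed master integer seed
#' @param tag character label of the consuming stage
#' @return integer seed
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483399 + 1)
}

# Evaluate expr with a local RNG state; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Merge 0-based half-open intervals given as a 2-column matrix; returns the
# sorted disjoint union.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in 2L:nrow(iv)) {
      j <- nrow(out)
      if (iv[i, 1L] <= out[j, 2L]) {
        out[j, 2L] <- max(out[j, 2L], iv[i, 2L])
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
      }
    }
  }
  colnames(out) <- c("start", "end")
  out
}

# Total length of the union of 0-based half-open intervals.
union_length <- function(iv) {
  m <- merge_intervals(iv)
  if (nrow(m) == 0L) return(0)
  sum(m[, 2L] - m[, 1L])
}

#' Encode/decode aligned-block lists
#'
#' Aligned segments travel in TSVs as `"start-end,start-end"` strings
#' (0-based half-open). `encode_blocks` takes a 2-column interval matrix;
#' `decode_blocks` inverts it (empty string = no blocks).
#'
#' @param iv 2-column numeric matrix of intervals
#' @param s encoded string
#' @return string / interval matrix
#' @export
encode_blocks <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return("")
  paste(paste0(iv[, 1L], "-", iv[, 2L]), collapse = ",")
}

#' @rdname encode_blocks
#' @export
decode_blocks <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

#' Adjusted Rand index between two partitions
#'
#' Cluster evaluation must be label-invariant; the ARI compares two label
#' vectors as partitions (1 = identical partition, ~0 = random agreement).
#'
#' @param x,y label vectors of equal length
#' @return numeric scalar
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  d <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(x), 2)
  expected <- b * d / n2
  maxi <- (b + d) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

geometric_mean <- function(x) exp(mean(log(x)))

# The six gene-relative insertion regions, in reporting order.
TE_REGIONS <- c("CDS", "UP2000", "INTRON", "DOWN2000", "DOWN200", "DOWN200_2000")

# The five TE classes considered throughout.
TE_TYPES <- c("DNA", "RC", "LTR", "LINE", "SINE")
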