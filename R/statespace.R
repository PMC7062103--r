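#' Encode a cultural state as its canonical integer index
#'
#' A cultural state is a vector of `n` binary traits `(s_1, ..., s_n)`. Its
#' canonical index is the value of the bit string `s_1 s_2 ... s_n` read as a
#' binary number with `s_1` the most significant bit, so `c(0,0,0,1,0,1)`
#' encodes to 5 and `c(1,0,0,1,0,1)` to 37.
#'
#' @param bits Integer (or logical) vector of 0/1 trait values, length `n >= 1`.
#' @return A single integer in `[0, 2^n - 1]`.
#' @seealso [state_decode()], [state_bitstring()]
#' @examples
#' state_encode(c(0, 0, 0, 1, 0, 1)) # 5
#' @export
state_encode <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L) {
    stop("`bits` must have length >= 1.", call. = FALSE)
  }
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must contain only 0 and 1.", call. = FALSE)
  }
  n <- length(bits)
  if (n <= 31) {
    as.integer(sum(bits * 2^((n - 1L):0L)))
  } else {
    sum(bits * 2^((n - 1L):0L))
  }
}

#' Decode a canonical state index into its trait vector
#'
#' Inverse of [state_encode()]: the index is expanded into `n` binary traits
#' with the first trait as the most significant bit.
#'
#' @param index Integer in `[0, 2^n - 1]`.
#' @param n Number of traits.
#' @return Integer vector of 0/1 values, length `n`.
#' @examples
#' state_decode(26, 6) # 0 1 1 0 1 0
#' @export
state_decode <- function(index, n) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1.", call. = FALSE)
  if (length(index) != 1L || is.na(index) || index < 0 || index >= 2^n ||
      index != floor(index)) {
    stop("`index` must be a single integer in [0, 2^n - 1].", call. = FALSE)
  }
  as.integer(floor(index / 2^((n - 1L):0L)) %% 2)
}

#' Format state indices as bit strings
#'
#' @param index Vector of state indices.
#' @param n Number of traits.
#' @return Character vector like `"011010"`.
#' @examples
#' state_bitstring(c(5, 37), 6)
#' @export
state_bitstring <- function(index, n) {
  vapply(index, function(i) paste(state_decode(i, n), collapse = ""),
         character(1))
}

#' Format states as "index (bitstring)" labels used in reports
#' @inheritParams state_bitstring
#' @return Character vector like `"26 (011010)"`.
#' @export
state_label <- function(index, n) {
  paste0(index, " (", state_bitstring(index, n), ")")
}

#' Hamming distance between cultural states
#'
#' The number of traits in which two states differ. Accepts either bit vectors
#' of equal length or (with `n` supplied) integer state indices, which may be
#' vectorized.
#'
#' @param s,s2 Bit vectors (when `n` is `NULL`) or state indices.
#' @param n Number of traits when indices are given.
#' @return Integer distance(s) in `[0, n]`.
#' @examples
#' hamming_distance(c(0, 0, 0, 1, 0, 1), c(1, 0, 0, 1, 0, 1)) # 1
#' hamming_distance(36, 26, n = 6) # 5
#' @export
hamming_distance <- function(s, s2, n = NULL) {
  if (is.null(n)) {
    if (length(s) != length(s2)) {
      stop("States must have the same number of traits.", call. = FALSE)
    }
    s <- as.integer(s); s2 <- as.integer(s2)
    if (!all(s %in% c(0L, 1L)) || !all(s2 %in% c(0L, 1L))) {
      stop("Trait values must be 0 or 1.", call. = FALSE)
    }
    return(sum(s != s2))
  }
  popcount(bitwXor(as.integer(s), as.integer(s2)))
}

# number of set bits; works on vectors of non-negative integers < 2^31
popcount <- function(v) {
  out <- integer(length(v))
  while (any(v > 0L)) {
    out <- out + (v %% 2L)
    v <- v %/% 2L
  }
  out
}

#' All nearest neighbours of a state on the trait hypercube
#'
#' Two states are neighbours when they differ in exactly one trait, so every
#' state has `n` neighbours.
#'
#' @param s Bit vector (when `n` is `NULL`) or state index.
#' @param n Number of traits when an index is given.
#' @return If `s` is a bit vector, an `n x n` integer matrix with one neighbour
#'   per row; if an index, an integer vector of the `n` neighbouring indices.
#' @examples
#' state_neighbors(0, n = 2) # states 10 and 01, i.e. indices 2 and 1
#' @export
state_neighbors <- function(s, n = NULL) {
  if (is.null(n)) {
    n <- length(s)
    state_encode(s) # validates the bit vector
    t(vapply(seq_len(n), function(i) {
      out <- as.integer(s)
      out[i] <- 1L - out[i]
      out
    }, integer(n)))
  } else {
    idx <- as.integer(s)
    if (idx < 0L || idx >= 2^n) stop("State index out of range.", call. = FALSE)
    bitwXor(idx, as.integer(2^((n - 1L):0L)))
  }
}

#' Enumerate all cultural states for n traits
#'
#' @param n Number of traits.
#' @param cap Safety cap on `n` guarding against accidental exponential
#'   blow-up; raise it explicitly for larger state spaces.
#' @return A tibble with one row per state in canonical index order: `index`
#'   and `bitstring`.
#' @examples
#' enumerate_states(3)
#' @export
enumerate_states <- function(n, cap = 16L) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1.", call. = FALSE)
  if (n > cap) {
    stop(sprintf("n = %d exceeds the state-space cap (%d); raise `cap` to allow 2^%d states.",
                 n, cap, n), call. = FALSE)
  }
  idx <- 0:(2^n - 1L)
  tibble::tibble(index = idx, bitstring = state_bitstring(idx, n))
}

#' Edge list of the trait hypercube
#'
#' Each undirected edge joins two states at Hamming distance 1; for `n` traits
#' there are `n * 2^(n-1)` edges.
#'
#' @inheritParams enumerate_states
#' @return A tibble with columns `from` and `to` (state indices, `from < to`).
#' @export
hypercube_edges <- function(n, cap = 16L) {
  states <- enumerate_states(n, cap = cap)$index
  purrr::map_dfr(seq_len(n), function(i) {
    mask <- as.integer(2^(n - i))
    from <- states[bitwAnd(states, mask) == 0L]
    tibble::tibble(from = from, to = bitwXor(from, mask))
  }) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Pairwise Hamming-distance matrix of the full state space
#'
#' @inheritParams enumerate_states
#' @return A `2^n x 2^n` integer matrix.
#' @keywords internal
hamming_matrix <- function(n) {
  idx <- 0:(2^n - 1L)
  matrix(popcount(bitwXor(rep(idx, times = length(idx)),
                          rep(idx, each = length(idx)))),
         nrow = length(idx))
}
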