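# Internal helpers: deterministic seeds and integer apportionment.

#' Derive a reproducible child seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary set of labels (year,
#' county, race group, ...) into a 31-bit integer, so that per-stratum draws
#' are reproducible and independent of the order in which strata are visited.
#' Uses a djb2-style rolling hash computed in double precision (exact below
#' 2^53) reduced modulo 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param ... Further labels (coerced to character) mixed into the hash.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @keywords internal
child_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 5381
  for (b in utf8ToInt(key)) h <- (h * 33 + b) %% 2147483647
  as.integer(h) + 1L
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Distributes an integer total across units proportionally to `quota`,
#' rounding so the units sum to the total exactly. Fractional-part ties are
#' broken by larger `tie_size`, then by lexicographic `tie_id` order.
#'
#' @param total Integer amount to distribute (>= 0).
#' @param quota Non-negative real shares; the allocation is proportional to
#'   `quota / sum(quota)`. Each unit receives at most `ceiling` of its exact
#'   share, so a unit with quota `q` never receives more than `ceiling(q *
#'   total / sum(quota))`.
#' @param tie_size,tie_id Tie-breakers for equal fractional parts.
#' @return Integer vector summing to `total`.
#' @keywords internal
largest_remainder <- function(total, quota,
                              tie_size = quota,
                              tie_id = seq_along(quota)) {
  stopifnot(total >= 0, all(quota >= 0))
  if (total == 0 || sum(quota) == 0) return(integer(length(quota)))
  exact <- quota * (total / sum(quota))
  out <- floor(exact)
  short <- total - sum(out)
  if (short > 0) {
    frac <- exact - out
    ord <- order(-frac, -xtfrm(tie_size), xtfrm(tie_id))
    out[ord[seq_len(short)]] <- out[ord[seq_len(short)]] + 1
  }
  as.integer(out)
}

# Sample `size` values from `x` without replacement, immune to the
# scalar-`x` surprise of base sample().
sample_exact <- function(x, size) {
  x[sample.int(length(x), size)]
}
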