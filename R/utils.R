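`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize a non-negative count/probability vector to sum 1
normalize_probs <- function(x, what = "probability vector") {
  if (any(!is.finite(x)) || any(x < 0) || sum(x) <= 0)
    stop("invalid ", what, call. = FALSE)
  x / sum(x)
}
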