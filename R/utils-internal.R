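# Internal helpers shared across modules.

# Fixed condition order used everywhere: rows of loading matrices, softmax
# classes, contribution tables.
CONDITIONS <- c("noun", "verb", "object", "implied_action")

# Word trials present written stimuli (nouns, verbs); picture trials present
# pictorial stimuli (plain objects, objects with action-implying hands).
conditionModality <- function(condition) {
  out <- ifelse(condition %in% c("noun", "verb"), "word", "picture")
  out[!condition %in% CONDITIONS] <- NA_character_
  out
}

# Binary action contrast: verbs and implied actions are "action", nouns and
# plain objects are "non_action".
conditionBinary <- function(condition) {
  out <- ifelse(condition %in% c("verb", "implied_action"), "action", "non_action")
  out[!condition %in% CONDITIONS] <- NA_character_
  out
}

# Deterministic per-stage seed derivation from one global seed, kept below
# 2^31 - 1 so set.seed() always accepts it.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 97L * h) %% 2147483629)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Population (divide-by-n) standard deviation per column.
colSdPop <- function(x) {
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
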