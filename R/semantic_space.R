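#' Construct a semantic space
#'
#' A semantic space is a vocabulary of tokens, each carrying a D-dimensional
#' real embedding vector (word2vec-style). Token lookup is exact after
#' lower-casing; no fuzzy matching is attempted.
#'
#' @param vectors Numeric matrix with one row per token; row names are the
#'   tokens. Values must be finite.
#' @return An object of class `semantic_space` with fields `vectors` (the
#'   matrix, tokens lower-cased) and `dim` (number of embedding dimensions).
#' @export
semantic_space <- function(vectors) {
  assert_finite_matrix(vectors, "vectors")
  tokens <- rownames(vectors)
  if (is.null(tokens) || anyNA(tokens) || any(tokens == "")) {
    stop_semdec("`vectors` must have non-empty row names (the tokens).",
                "semdecode_validation_error")
  }
  rownames(vectors) <- tolower(tokens)
  if (anyDuplicated(rownames(vectors))) {
    stop_semdec("Duplicated tokens after lower-casing.", "semdecode_validation_error")
  }
  structure(list(vectors = vectors, dim = ncol(vectors)), class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space: %d tokens, %d dimensions>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @export
dim.semantic_space <- function(x) dim(x$vectors)

#' Look up token vectors in a semantic space
#'
#' @param space A [semantic_space()].
#' @param tokens Character vector of tokens (case-insensitive).
#' @return Matrix `length(tokens) x D`, rows named by the (lower-cased) tokens.
#' @export
lookup_vectors <- function(space, tokens) {
  stopifnot(inherits(space, "semantic_space"))
  tok <- tolower(tokens)
  miss <- setdiff(unique(tok), rownames(space$vectors))
  if (length(miss) > 0) {
    stop_semdec(paste0("Token(s) not present in the semantic space: ",
                       paste(miss, collapse = ", ")),
                "semdecode_missing_token_error")
  }
  space$vectors[tok, , drop = FALSE]
}

#' Read word vectors in word2vec text format
#'
#' The text dialect has a header line `"<vocab_size> <dim>"` followed by one
#' line per token: the token and `dim` whitespace-separated floats.
#'
#' @param path Path to a word2vec text file.
#' @return A [semantic_space()].
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path)) {
    stop_semdec(sprintf("File not found: %s", path), "semdecode_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) {
    stop_semdec(sprintf("%s: empty file.", path), "semdecode_format_error")
  }
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[1L]))
  d <- suppressWarnings(as.integer(header[2L]))
  if (length(header) != 2L || is.na(n) || is.na(d) || n < 1L || d < 1L) {
    stop_semdec(sprintf("%s: malformed word2vec header on line 1: \"%s\"",
                        path, lines[[1L]]), "semdecode_format_error")
  }
  if (length(lines) - 1L != n) {
    stop_semdec(sprintf("%s: header declares %d tokens but %d rows found.",
                        path, n, length(lines) - 1L), "semdecode_format_error")
  }
  vecs <- matrix(NA_real_, nrow = n, ncol = d)
  tokens <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1L]]
    if (length(parts) != d + 1L) {
      stop_semdec(sprintf("%s: line %d has %d fields, expected %d (token + %d values).",
                          path, i + 1L, length(parts), d + 1L, d),
                  "semdecode_format_error")
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) {
      stop_semdec(sprintf("%s: non-numeric vector component on line %d.", path, i + 1L),
                  "semdecode_format_error")
    }
    tokens[i] <- parts[1L]
    vecs[i, ] <- vals
  }
  rownames(vecs) <- tokens
  semantic_space(vecs)
}

#' Write a semantic space in word2vec text format
#'
#' @param space A [semantic_space()].
#' @param path Output file path.
#' @param digits Significant digits used for the components (default 17,
#'   enough for an exact double round trip).
#' @return Invisibly, `path`.
#' @export
write_word2vec <- function(space, path, digits = 17) {
  stopifnot(inherits(space, "semantic_space"))
  v <- space$vectors
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(rownames(v)[i],
          paste(formatC(v[i, ], format = "g", digits = digits), collapse = " "))
  }, character(1))
  writeLines(c(paste(nrow(v), ncol(v)), body), path)
  invisible(path)
}

#' The six semantic coordinate models
#'
#' Enumerates the feature-combination models under which a trial's semantic
#' coordinate can be constructed:
#' \describe{
#'   \item{CLUE3}{vector of the third (most distinctive, guess-triggering) clue}
#'   \item{CLUE123}{sum of the trial's three clue vectors}
#'   \item{TARGET}{vector of the target word itself}
#'   \item{ALL_FEATURES}{sum over every norm feature of the target}
#'   \item{MIXED_CLUES}{sum of the three clue vectors of a donor trial of the
#'     same target whose clues are disjoint from this trial's}
#'   \item{ALL_NONCLUES}{sum over all norm features excluding the nine
#'     clue-flagged ones}
#' }
#'
#' @return Character vector of the six model names.
#' @export
coordinate_models <- function() {
  c("CLUE3", "CLUE123", "TARGET", "ALL_FEATURES", "MIXED_CLUES", "ALL_NONCLUES")
}

resolve_tokens <- function(texts, map) {
  idx <- match(texts, map$text)
  if (anyNA(idx)) {
    stop_semdec(paste0("Feature(s) with no key-word mapping: ",
                       paste(texts[is.na(idx)], collapse = ", ")),
                "semdecode_missing_token_error")
  }
  map$token[idx]
}

#' Sum the key-word vectors of a set of features
#'
#' Resolves each feature text to its single key-word token through the keyword
#' map and returns the component-wise sum of the corresponding vectors.
#' No length normalization is applied, so linear identities such as
#' `ALL_FEATURES = ALL_NONCLUES + sum(clue vectors)` hold exactly.
#'
#' @param features Character vector of feature texts.
#' @param map Keyword map: a data frame with columns `text` and `token`.
#' @param space A [semantic_space()].
#' @return Numeric vector of length `space$dim`.
#' @export
sum_feature_vectors <- function(features, map, space) {
  tokens <- resolve_tokens(features, map)
  v <- lookup_vectors(space, tokens)
  colSums(v)
}

#' Semantic coordinate of one trial under a coordinate model
#'
#' @param trial A single trial record (one-row data frame or list) with fields
#'   `target`, `clue1`, `clue2`, `clue3` and, for `MIXED_CLUES`, `donor`.
#' @param model One of [coordinate_models()].
#' @param norms Feature norms: data frame with columns `target`, `feature`,
#'   `rank` (1 = least distinctive) and `is_clue`.
#' @param map Keyword map (`text`, `token`).
#' @param space A [semantic_space()].
#' @param trials Full trial table; required for `MIXED_CLUES` to resolve the
#'   donor trial's clues.
#' @return Numeric vector of length `space$dim`. An `ALL_NONCLUES` request for
#'   a target whose features are all clue-flagged returns the zero vector with
#'   a degenerate-coordinate warning.
#' @export
trial_coordinate <- function(trial, model, norms, map, space, trials = NULL) {
  model <- match.arg(model, coordinate_models())
  trial <- as.list(trial)
  tgt <- trial$target
  feats <- norms[norms$target == tgt, , drop = FALSE]
  if (nrow(feats) == 0) {
    stop_semdec(sprintf("Target '%s' not present in the feature norms.", tgt),
                "semdecode_validation_error")
  }
  switch(model,
    CLUE3 = as.numeric(lookup_vectors(space, resolve_tokens(trial$clue3, map))),
    CLUE123 = sum_feature_vectors(c(trial$clue1, trial$clue2, trial$clue3), map, space),
    TARGET = as.numeric(lookup_vectors(space, resolve_tokens(tgt, map))),
    ALL_FEATURES = sum_feature_vectors(feats$feature, map, space),
    ALL_NONCLUES = {
      nc <- feats$feature[!feats$is_clue]
      if (length(nc) == 0) {
        warn(sprintf("Target '%s' has no non-clue features; ALL_NONCLUES coordinate is the zero vector.", tgt),
             class = "semdecode_degenerate_coordinate_warning")
        rep(0, space$dim)
      } else {
        sum_feature_vectors(nc, map, space)
      }
    },
    MIXED_CLUES = {
      if (is.null(trial$donor) || is.na(trial$donor)) {
        stop_semdec("MIXED_CLUES requires a donor trial id on the trial record.",
                    "semdecode_configuration_error")
      }
      if (is.null(trials)) {
        stop_semdec("MIXED_CLUES requires the full trial table (`trials`) to resolve the donor.",
                    "semdecode_configuration_error")
      }
      donor <- trials[trials$trial == trial$donor, , drop = FALSE]
      if (nrow(donor) != 1) {
        stop_semdec(sprintf("Donor trial '%s' not found in the trial table.", trial$donor),
                    "semdecode_configuration_error")
      }
      own <- c(trial$clue1, trial$clue2, trial$clue3)
      dcl <- c(donor$clue1, donor$clue2, donor$clue3)
      if (length(intersect(own, dcl)) > 0) {
        stop_semdec(sprintf("Donor trial '%s' shares clues with trial '%s'.",
                            trial$donor, trial$trial),
                    "semdecode_configuration_error")
      }
      sum_feature_vectors(dcl, map, space)
    }
  )
}

#' Semantic design matrix over a trial table
#'
#' Builds the `n x D` matrix of semantic coordinates entered into the zero-shot
#' regression: one row per trial (`level = "trial"`) or one row per target
#' (`level = "target"`, meaningful for the trial-invariant `TARGET` and
#' `ALL_FEATURES` models, used with repetition-averaged data). Row order
#' follows trial order (or first-appearance target order).
#'
#' @inheritParams trial_coordinate
#' @param trials Trial table (see [assemble_trials()]).
#' @param level `"trial"` or `"target"`.
#' @return Numeric matrix with row names (trial or target ids).
#' @export
design_matrix <- function(trials, model, norms, map, space,
                          level = c("trial", "target")) {
  level <- match.arg(level)
  model <- match.arg(model, coordinate_models())
  if (is.null(trials) || nrow(trials) == 0) {
    stop_semdec("Empty trial table.", "semdecode_validation_error")
  }
  if (level == "target") {
    if (!model %in% c("TARGET", "ALL_FEATURES")) {
      stop_semdec("Target-level design matrices are defined for the trial-invariant TARGET and ALL_FEATURES models only.",
                  "semdecode_validation_error")
    }
    targets <- unique(trials$target)
    rows <- lapply(targets, function(tg) {
      trial_coordinate(trials[match(tg, trials$target), ], model, norms, map, space,
                       trials = trials)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- targets
  } else {
    rows <- lapply(seq_len(nrow(trials)), function(i) {
      trial_coordinate(trials[i, ], model, norms, map, space, trials = trials)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- trials$trial
  }
  out
}
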