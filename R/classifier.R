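#' Train a hairpin classifier on triplet features
#'
#' Fits a probabilistic linear classifier (regularized logistic regression
#' via iteratively reweighted least squares with a small ridge penalty, so
#' perfectly separable classes remain numerically stable) on the
#' 32-dimensional triplet feature vectors of positive (genuine precursor)
#' and negative (tRNA/CDS-derived pseudo-hairpin) examples. The probability
#' is a monotone function of the linear margin, as the downstream
#' acceptance threshold assumes.
#'
#' Structures are computed with the built-in folding engine when the inputs
#' are bare sequences.
#'
#' @param positives,negatives character vectors of sequences, or data.frames
#'   with `sequence` and `structure` columns.
#' @param ridge ridge penalty on the coefficients (default 1e-5; small enough
#'   that clearly separable classes yield saturated probabilities).
#' @param rng_seed seed recorded in the model (training itself is
#'   deterministic).
#' @return object of class `hairpin_classifier` with elements
#'   `coefficients`, `feature_names`, `ridge`, `rng_seed`, `version`.
#' @export
train_hairpin_classifier <- function(positives, negatives, ridge = 1e-5,
                                     rng_seed = 1L) {
  n_of <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
  if (!n_of(positives) || !n_of(negatives)) {
    stop("both classes must be non-empty")
  }
  xp <- feature_matrix(positives)
  xn <- feature_matrix(negatives)
  x <- rbind(xp, xn)
  y <- c(rep(1, nrow(xp)), rep(0, nrow(xn)))
  set.seed(rng_seed)
  beta <- ridge_logistic(cbind(1, x), y, ridge)
  structure(list(coefficients = stats::setNames(beta, c("(Intercept)", colnames(x))),
                 feature_names = colnames(x), ridge = ridge,
                 rng_seed = as.integer(rng_seed), version = "1"),
            class = "hairpin_classifier")
}

feature_matrix <- function(input) {
  if (is.character(input)) {
    input <- data.frame(sequence = input, stringsAsFactors = FALSE)
  }
  if (is.null(input$structure)) {
    input$structure <- vapply(input$sequence,
                              function(s) fold_sequence(s)$structure,
                              character(1))
  }
  t(mapply(triplet_features, input$sequence, input$structure))
}

# IRLS for ridge-penalized logistic regression; intercept unpenalized
ridge_logistic <- function(X, y, lambda, max_iter = 100L, tol = 1e-9) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new); break
    }
    beta <- drop(beta_new)
  }
  beta
}

#' @export
print.hairpin_classifier <- function(x, ...) {
  cat("Hairpin triplet classifier (v", x$version, "), ",
      length(x$feature_names), " features, ridge ", x$ridge, "\n", sep = "")
  invisible(x)
}

#' Predict hairpin probabilities
#'
#' @param object a [train_hairpin_classifier()] model.
#' @param newdata sequences or a data.frame with sequence/structure.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.hairpin_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  x <- x[, object$feature_names, drop = FALSE]
  drop(stats::plogis(cbind(1, x) %*% object$coefficients))
}

#' Classify hairpin candidates
#'
#' Accepts a candidate iff its probability is strictly greater than
#' `threshold` (the default reproduces the conventional 0.998 operating
#' point; the inequality is strict, so a probability of exactly 0.998 is
#' rejected).
#'
#' @param candidates a `hairpin_candidates` data.frame (or anything
#'   [predict.hairpin_classifier()] accepts).
#' @param classifier a trained `hairpin_classifier`.
#' @param threshold acceptance threshold on the probability.
#' @return data.frame: probability, threshold, accepted (plus the candidate
#'   columns when a data.frame was supplied).
#' @export
classify_hairpins <- function(candidates, classifier, threshold = 0.998) {
  if (!inherits(classifier, "hairpin_classifier")) {
    stop("untrained or invalid classifier")
  }
  prob <- predict(classifier, candidates)
  dec <- data.frame(probability = prob, threshold = threshold,
                    accepted = prob > threshold)
  if (is.data.frame(candidates)) {
    dec <- cbind(candidates[, setdiff(names(candidates), "loops"),
                            drop = FALSE], dec)
  }
  rownames(dec) <- NULL
  dec
}

#' Persist / restore a hairpin classifier
#'
#' The model file is plain text: a version header followed by one
#' coefficient per line.
#'
#' @param model a `hairpin_classifier`.
#' @param path file path.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "hairpin_classifier"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hairpin_classifier v%s ridge=%g seed=%d",
                     model$version, model$ridge, model$rng_seed), con)
  utils::write.table(
    data.frame(feature = names(model$coefficients),
               coefficient = unname(model$coefficients)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# hairpin_classifier v", header)) {
    stop("not a hairpin_classifier model file")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           stringsAsFactors = FALSE)
  coef <- stats::setNames(tab$coefficient, tab$feature)
  structure(list(coefficients = coef,
                 feature_names = setdiff(names(coef), "(Intercept)"),
                 ridge = as.numeric(sub(".*ridge=([0-9.e+-]+).*", "\\1", header)),
                 rng_seed = as.integer(sub(".*seed=([0-9]+).*", "\\1", header)),
                 version = sub(".*hairpin_classifier v([0-9.]+).*", "\\1", header)),
            class = "hairpin_classifier")
}

#' Surrogate Drosha-site score
#'
#' A structure-only stand-in for a Microprocessor/Drosha processing-site
#' model (the original is proprietary software and is NOT reproduced here;
#' this surrogate is not equivalent to it). The score combines the length
#' of the stem supporting the putative cleavage site with the loop
#' structure: `score = 22 - (number of base pairs) + 10 * (extra terminal
#' loops) - 0.5`. A canonical hairpin -- a single terminal loop on a stem of
#' at least 22 base pairs, enough helix to span the ~2-helical-turn lower
#' stem Drosha requires -- scores below zero (accept); a structureless
#' candidate scores 21.5 (reject). The decision depends on structure only,
#' never on sequence identity.
#'
#' @param candidate a dot-bracket string, or a list/data.frame row with a
#'   `structure` element.
#' @return numeric score; accept iff `score < 0`.
#' @export
drosha_site_score <- function(candidate) {
  structure_db <- if (is.character(candidate)) candidate else candidate$structure
  if (is.null(structure_db)) stop("candidate has no structure")
  vapply(structure_db, function(db) {
    st <- strsplit(db, "")[[1]]
    n_bp <- sum(st == "(")
    n_terminal <- count_terminal_loops(st)
    22 - n_bp + 10 * max(n_terminal - 1L, 0L) - 0.5
  }, numeric(1), USE.NAMES = FALSE)
}

# a terminal (hairpin) loop is a "(...)" with no brackets inside
count_terminal_loops <- function(st) {
  n <- 0L
  open <- FALSE
  for (ch in st) {
    if (ch == "(") open <- TRUE
    else if (ch == ")") {
      if (open) n <- n + 1L
      open <- FALSE
    }
  }
  n
}
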