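#' Logistic biomarker panel model
#'
#' A named linear predictor over a miRNA subset:
#' `logit(P) = a + b1*X1 + ... + bn*Xn`, where the `X` are expression
#' values of the panel features and `P` is the probability of the
#' positive outcome (here, survival).
#'
#' @param features character vector of feature IDs (the `X` order).
#' @param intercept numeric intercept `a`.
#' @param coefficients numeric vector, one coefficient per feature.
#' @return object of class `panel_model`.
#' @examples
#' m <- panel_model(c("f1", "f2"), intercept = 0.5, coefficients = c(1, -2))
#' predict(m, c(f1 = 0, f2 = 0))           # log-odds 0.5
#' predict(m, c(f1 = 0, f2 = 0), "response")
#' @export
panel_model <- function(features, intercept, coefficients) {
  features <- as.character(features)
  stopifnot(length(coefficients) == length(features),
            length(intercept) == 1L,
            is.finite(intercept), all(is.finite(coefficients)))
  structure(
    list(features = features, intercept = as.numeric(intercept),
         coefficients = setNames(as.numeric(coefficients), features)),
    class = "panel_model"
  )
}

#' @rdname panel_model
#' @param object a `panel_model`.
#' @param newdata named numeric vector, or matrix/data frame with one
#'   column (or row-wise columns) per panel feature.
#' @param type `"link"` for log-odds (default) or `"response"` for the
#'   probability `1 / (1 + exp(-log_odds))`.
#' @param ... unused.
#' @export
predict.panel_model <- function(object, newdata, type = c("link", "response"),
                                ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  if (!all(object$features %in% colnames(newdata))) {
    stop("newdata must provide a value for every panel feature: ",
         paste(setdiff(object$features, colnames(newdata)), collapse = ", "))
  }
  eta <- drop(object$intercept +
              newdata[, object$features, drop = FALSE] %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' @rdname panel_model
#' @export
coef.panel_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.panel_model <- function(x, ...) {
  terms <- sprintf("%+.3g*%s", x$coefficients, x$features)
  cat("logit(P) =", sprintf("%.3g", x$intercept), paste(terms, collapse = " "),
      "\n")
  invisible(x)
}

#' Published prognostic RRiF panels
#'
#' The two reported logistic panels scoring the risk of radiation-induced
#' fatality (chance to survive as the positive class): the three-miRNA
#' panel selected by the k-fold route and the seven-miRNA panel selected
#' by the repeated 70:30 split (RSBMR) route. Useful as worked examples
#' and for scoring new expression profiles on the published coefficients.
#'
#' @return named list of two [panel_model()] objects, `kfold_3mir` and
#'   `rsbmr_7mir`.
#' @examples
#' p <- published_rrif_panels()
#' predict(p$kfold_3mir, setNames(rep(0, 3), p$kfold_3mir$features))
#' @export
published_rrif_panels <- function() {
  list(
    kfold_3mir = panel_model(
      features = c("miR-376c-3p", "miR-342-3p", "miR-363-3p"),
      intercept = 0.58,
      coefficients = c(-0.41, -0.38, -0.68)
    ),
    rsbmr_7mir = panel_model(
      features = c("miR-92b-3p", "miR-106b-3p", "miR-143-3p", "miR-23a-3p",
                   "miR-28-3p", "miR-342-3p", "miR-363-3p"),
      intercept = 0.19,
      coefficients = c(0.41, -0.47, 0.50, 0.84, -1.98, -0.47, 0.70)
    )
  )
}
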