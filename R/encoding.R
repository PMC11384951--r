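## Leakage-safe transformation of heterogeneous features into a scaled
## continuous space: smoothed target-mean encoding for discrete features
## (fitted against the SOFA total), then standard scaling — both fitted on
## training rows only.

#' Fit a smoothed target-mean encoder for discrete features
#'
#' Each category of each discrete feature is mapped to
#' `(sum of its training targets + smoothing * prior) / (count + smoothing)`,
#' where the prior is the global training-target mean. Unseen categories map
#' to the prior at transform time. With a single category everywhere the
#' encoding equals the global target mean for any smoothing.
#'
#' @param train data.frame of training rows.
#' @param target numeric training target (the SOFA total in the pipeline).
#' @param discrete_cols names of columns to encode.
#' @param smoothing prior-count smoothing weight (default 1).
#' @param train_ids optional row identifiers recorded for the leakage audit.
#' @return An [EncoderState-class] with the encoding part filled.
#' @export
fitTargetEncoder <- function(train, target, discrete_cols,
                             smoothing = 1, train_ids = rownames(train)) {
  if (nrow(train) == 0L) stop("empty training set")
  stopifnot(length(target) == nrow(train), all(discrete_cols %in% names(train)))
  prior <- mean(target)
  encodings <- lapply(discrete_cols, function(cn) {
    lv <- as.character(train[[cn]])
    sums <- tapply(target, lv, sum)
    cnts <- tapply(target, lv, length)
    enc <- (sums + smoothing * prior) / (cnts + smoothing)
    stats::setNames(as.numeric(enc), names(sums))
  })
  names(encodings) <- discrete_cols
  new("EncoderState",
      encodings = encodings, prior = prior, smoothing = smoothing,
      center = numeric(), scale = numeric(),
      columns = discrete_cols, discreteColumns = discrete_cols,
      trainIds = as.character(train_ids %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

applyEncodings <- function(df, enc) {
  for (cn in enc@discreteColumns) {
    if (!cn %in% names(df)) next
    lv <- as.character(df[[cn]])
    e <- enc@encodings[[cn]]
    v <- unname(e[lv])
    v[is.na(v)] <- enc@prior  # unseen category -> prior
    df[[cn]] <- v
  }
  df
}

#' Fit standard-scaling parameters on training rows
#'
#' Per-column center = training mean, spread = training standard deviation;
#' zero-spread columns get spread 1 so constant features scale to all zeros
#' rather than NaN.
#'
#' @param train data.frame of numeric training columns.
#' @param cols columns to fit (default all).
#' @param train_ids optional row identifiers recorded for the leakage audit.
#' @return An [EncoderState-class] with the scaling part filled.
#' @export
fitScaler <- function(train, cols = names(train),
                      train_ids = rownames(train)) {
  center <- vapply(cols, function(cn) mean(train[[cn]]), numeric(1))
  spread <- vapply(cols, function(cn) sd(train[[cn]]), numeric(1))
  spread[is.na(spread) | spread == 0] <- 1
  new("EncoderState",
      encodings = list(), prior = NA_real_, smoothing = NA_real_,
      center = center, scale = spread,
      columns = cols, discreteColumns = character(),
      trainIds = as.character(train_ids %||% character()))
}

#' Fit the full encoder: target encoding followed by standard scaling
#'
#' Discrete (and pathogen) columns are target-encoded first; scaling
#' parameters are then fitted on the encoded training table, so every column
#' of the transformed training data has mean 0 and unit spread. All fitted
#' statistics derive exclusively from the training rows.
#'
#' @inheritParams fitTargetEncoder
#' @return An [EncoderState-class] with both parts filled.
#' @export
fitEncoder <- function(train, target, discrete_cols = character(),
                       smoothing = 1, train_ids = rownames(train)) {
  te <- fitTargetEncoder(train, target, discrete_cols, smoothing, train_ids)
  encoded <- applyEncodings(train, te)
  sc <- fitScaler(encoded, names(train), train_ids)
  new("EncoderState",
      encodings = te@encodings, prior = te@prior, smoothing = smoothing,
      center = sc@center, scale = sc@scale,
      columns = names(train), discreteColumns = discrete_cols,
      trainIds = as.character(train_ids %||% character()))
}

#' Transform a table with a fitted encoder
#'
#' Applies the stored category encodings and scaling parameters. The
#' transform is deterministic, preserves column order, never produces
#' missing or non-finite output, and uses only training statistics — for
#' held-out rows just as for training rows.
#'
#' @param df data.frame whose columns are a subset of the fitted columns.
#' @param encoder a fitted [EncoderState-class].
#' @return numeric matrix of encoded, scaled features.
#' @export
encodeFeatures <- function(df, encoder) {
  missing <- setdiff(names(df), encoder@columns)
  if (length(missing)) {
    stop("column(s) absent from the fitted encoder: ",
         paste(missing, collapse = ", "))
  }
  df <- applyEncodings(df, encoder)
  out <- vapply(names(df), function(cn) {
    if (length(encoder@center)) {
      (as.numeric(df[[cn]]) - encoder@center[[cn]]) / encoder@scale[[cn]]
    } else {
      as.numeric(df[[cn]])
    }
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  rownames(out) <- rownames(df)
  if (any(!is.finite(out))) stop("encoder produced non-finite output")
  out
}

#' Invert the scaling step for continuous columns
#'
#' Closed-form inverse of the standard scaling (`x * spread + center`);
#' category encodings are not invertible and are returned as encoded.
#'
#' @param mat matrix produced by [encodeFeatures()].
#' @param encoder the fitted [EncoderState-class].
#' @return matrix on the original scale.
#' @export
inverseScale <- function(mat, encoder) {
  for (cn in colnames(mat)) {
    mat[, cn] <- mat[, cn] * encoder@scale[[cn]] + encoder@center[[cn]]
  }
  mat
}

#' Encode a cohort's state vectors for distance analysis
#'
#' Fits the encoder on the training patients' state vectors (all patients by
#' default) with the SOFA total as the encoding target, then transforms every
#' state vector of the cohort. Feature kinds come from `schema` or, when
#' omitted, from the cohort's `rowData`; everything not continuous is
#' target-encoded.
#'
#' @param cohort a [SepsisCohort-class].
#' @param schema optional data.frame (`feature`, `kind`).
#' @param train_patients patient ids to fit on (default: all).
#' @param smoothing target-encoder smoothing weight.
#' @return list with `matrix` (states x features, encoded + scaled) and
#'   `encoder` (the fitted [EncoderState-class]).
#' @export
encodeStates <- function(cohort, schema = NULL, train_patients = NULL,
                         smoothing = 1) {
  wide <- as.data.frame(stateMatrix(cohort), check.names = FALSE)
  kinds <- if (is.null(schema)) {
    stats::setNames(as.character(rowData(cohort)$kind), rownames(cohort))
  } else {
    stats::setNames(schema$kind, schema$feature)
  }
  discrete <- names(kinds)[kinds != "continuous"]
  cd <- colData(cohort)
  trainRows <- if (is.null(train_patients)) {
    seq_len(nrow(wide))
  } else {
    which(cd$patient_id %in% train_patients)
  }
  enc <- fitEncoder(wide[trainRows, , drop = FALSE],
                    target = cd$sofa_total[trainRows],
                    discrete_cols = intersect(discrete, names(wide)),
                    smoothing = smoothing,
                    train_ids = rownames(wide)[trainRows])
  list(matrix = encodeFeatures(wide, enc), encoder = enc)
}
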