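# Dataset container: a versioned JSON text format. Hypercomplex arrays and
# all numeric metadata are encoded as "%.17g" strings, which round-trip
# IEEE doubles bitwise through as.numeric(); plain JSON numbers do not.
#
# Layout (schema_version 1):
#   schema            "hyperwdecon-dataset"
#   schema_version    1
#   type              "interferogram" | "spectrum2d"
#   interferogram:  scheme{...}, role, meta{tagged values},
#                   components{dim, cos_re, cos_im, sin_re, sin_im}
#   spectrum2d:     axes{axis1, axis2}, intensity{dim, values},
#                   processing{tagged values}

DATASET_SCHEMA <- "hyperwdecon-dataset"
DATASET_VERSION <- 1L
MODEL_SCHEMA <- "hyperwdecon-estimator"
MODEL_VERSION <- 1L

enc_value <- function(x) {
  if (inherits(x, "hw_decay_model"))
    list(.t = "decay_model", epsilon = num_to_chr(x$epsilon),
         rate = num_to_chr(x$rate), offset = num_to_chr(x$offset))
  else if (inherits(x, "hw_scheme"))
    list(.t = "scheme", v = lapply(unclass(x), num_to_chr))
  else if (is.numeric(x)) list(.t = "num", v = num_to_chr(x))
  else if (is.character(x)) list(.t = "chr", v = x)
  else if (is.logical(x)) list(.t = "lgl", v = x)
  else if (is.null(x)) list(.t = "null")
  else if (is.list(x)) list(.t = "list", v = lapply(x, enc_value))
  else stop_hw("cannot serialize value of class ", class(x)[1],
               class = "hw_format_error")
}

dec_value <- function(x) {
  switch(x$.t,
    decay_model = decay_model(chr_to_num(x$epsilon), chr_to_num(x$rate),
                              chr_to_num(x$offset)),
    scheme = {
      v <- lapply(x$v, chr_to_num)
      acq_scheme(v$n_t1_complex, v$dt1, v$n_t2, v$dt2, v$scans_per_fid,
                 v$recycle_delay, v$acq_window)
    },
    num = chr_to_num(unlist(x$v)),
    chr = unlist(x$v),
    lgl = unlist(x$v),
    null = NULL,
    list = lapply(x$v, dec_value),
    stop_hw("unknown tagged value type '", x$.t, "'",
            class = "hw_format_error")
  )
}

#' Write an interferogram or spectrum to the dataset container
#'
#' The container is a versioned JSON text file; all numeric content is
#' stored at full precision and round-trips bitwise, including any
#' ground-truth decay model recorded in the metadata of synthetic data.
#'
#' @param path Output file path.
#' @param x An [interferogram()] or a [process_spectrum()] result.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(path, x) {
  if (inherits(x, "hw_interferogram")) {
    obj <- list(
      schema = DATASET_SCHEMA, schema_version = DATASET_VERSION,
      type = "interferogram",
      scheme = lapply(unclass(x$scheme), num_to_chr),
      role = x$role,
      meta = lapply(x$meta, enc_value),
      components = list(
        dim = dim(x$cos),
        cos_re = num_to_chr(as.vector(Re(x$cos))),
        cos_im = num_to_chr(as.vector(Im(x$cos))),
        sin_re = num_to_chr(as.vector(Re(x$sin))),
        sin_im = num_to_chr(as.vector(Im(x$sin)))
      )
    )
  } else if (inherits(x, "hw_spectrum2d")) {
    obj <- list(
      schema = DATASET_SCHEMA, schema_version = DATASET_VERSION,
      type = "spectrum2d",
      axes = list(axis1 = num_to_chr(x$axis1), axis2 = num_to_chr(x$axis2)),
      intensity = list(dim = dim(x$intensity),
                       values = num_to_chr(as.vector(x$intensity))),
      processing = lapply(x$processing, enc_value)
    )
  } else {
    stop_hw("write_dataset expects an interferogram or spectrum2d",
            class = "hw_format_error")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a dataset container written by [write_dataset()]
#'
#' @param path File path.
#' @return The stored [interferogram()] or `hw_spectrum2d`, reconstructed
#'   bitwise.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop_hw("no such file: ", path, class = "hw_format_error")
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE),
    error = function(e) stop_hw("corrupt or truncated dataset file: ",
                                conditionMessage(e),
                                class = "hw_format_error"))
  if (!identical(obj$schema, DATASET_SCHEMA))
    stop_hw("not a ", DATASET_SCHEMA, " file", class = "hw_format_error")
  if (!identical(as.integer(obj$schema_version), DATASET_VERSION))
    stop_hw("unsupported schema version ", obj$schema_version,
            " (supported: ", DATASET_VERSION, ")",
            class = "hw_version_error")
  if (identical(obj$type, "interferogram")) {
    sv <- lapply(obj$scheme, chr_to_num)
    scheme <- acq_scheme(sv$n_t1_complex, sv$dt1, sv$n_t2, sv$dt2,
                         sv$scans_per_fid, sv$recycle_delay, sv$acq_window)
    d <- as.integer(obj$components$dim)
    grab <- function(re, im)
      matrix(complex(real = chr_to_num(obj$components[[re]]),
                     imaginary = chr_to_num(obj$components[[im]])),
             d[1], d[2])
    interferogram(grab("cos_re", "cos_im"), grab("sin_re", "sin_im"),
                  scheme, role = obj$role,
                  meta = lapply(obj$meta, dec_value))
  } else if (identical(obj$type, "spectrum2d")) {
    d <- as.integer(obj$intensity$dim)
    structure(list(
      intensity = matrix(chr_to_num(obj$intensity$values), d[1], d[2]),
      axis1 = chr_to_num(obj$axes$axis1),
      axis2 = chr_to_num(obj$axes$axis2),
      processing = lapply(obj$processing, dec_value)
    ), class = "hw_spectrum2d")
  } else {
    stop_hw("unknown dataset type '", obj$type, "'",
            class = "hw_format_error")
  }
}

#' Serialize a trained rate estimator to a single text file
#'
#' Weights are stored at full precision; a reloaded model reproduces
#' predictions bitwise. The embedded training record (seed, losses, corpus
#' provenance) travels with the weights.
#'
#' @param model An [train_estimator()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_estimator <- function(model, path) {
  stopifnot(inherits(model, "hw_estimator"))
  obj <- list(
    schema = MODEL_SCHEMA, schema_version = MODEL_VERSION,
    sizes = model$net$sizes,
    W = lapply(model$net$W, function(w) list(dim = dim(w),
                                             v = num_to_chr(as.vector(w)))),
    b = lapply(model$net$b, num_to_chr),
    hidden = model$hidden, activation = model$activation,
    n_t1 = model$n_t1, input_length = model$input_length,
    t1_max = num_to_chr(model$t1_max),
    normalization = model$normalization, label_scale = model$label_scale,
    training = enc_value(model$training)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_estimator
#' @export
read_estimator <- function(path) {
  if (!file.exists(path))
    stop_hw("no such file: ", path, class = "hw_format_error")
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE),
    error = function(e) stop_hw("corrupt or truncated model file: ",
                                conditionMessage(e),
                                class = "hw_format_error"))
  if (!identical(obj$schema, MODEL_SCHEMA))
    stop_hw("not a ", MODEL_SCHEMA, " file", class = "hw_format_error")
  if (!identical(as.integer(obj$schema_version), MODEL_VERSION))
    stop_hw("unsupported model schema version ", obj$schema_version,
            class = "hw_version_error")
  net <- list(
    sizes = as.integer(unlist(obj$sizes)),
    W = lapply(obj$W, function(w)
      matrix(chr_to_num(unlist(w$v)), w$dim[[1]], w$dim[[2]])),
    b = lapply(obj$b, function(b) chr_to_num(unlist(b)))
  )
  structure(list(
    net = net, hidden = as.integer(unlist(obj$hidden)),
    activation = obj$activation, n_t1 = as.integer(obj$n_t1),
    input_length = as.integer(obj$input_length),
    t1_max = chr_to_num(obj$t1_max), normalization = obj$normalization,
    label_scale = obj$label_scale, training = dec_value(obj$training)
  ), class = "hw_estimator")
}
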