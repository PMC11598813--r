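# Weight-bundle and dataset serialization: JSON documents with binary
# masks packed bitwise and base64-encoded, batch-norm parameters and
# thresholds as decimals at full precision. Round-trips reproduce identical
# classifications.

.pack_bits_b64 <- function(m) {
  bits <- as.logical(as.vector(m))
  pad <- (8L - length(bits) %% 8L) %% 8L
  jsonlite::base64_enc(packBits(c(bits, rep(FALSE, pad))))
}

.unpack_bits_b64 <- function(b64, nr, nc) {
  bits <- as.integer(rawToBits(jsonlite::base64_dec(b64)))
  matrix(bits[seq_len(nr * nc)], nr, nc)
}

.bn_to_list <- function(bn) lapply(as.list(bn), unname)

.bn_from_list <- function(l) data.frame(gamma = l$gamma, beta = l$beta,
                                        mu = l$mu, sigma = l$sigma)

#' Write a model bundle
#'
#' Serializes reference weights (`bdscnn_weights`) or a folded model
#' (`bdscnn_folded`) to a single JSON document: shapes and configuration in
#' clear, 0/1 masks packed and base64-encoded, real parameters at full
#' decimal precision.
#'
#' @param model A `bdscnn_weights` or `bdscnn_folded` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bundle <- function(model, path) {
  cfg <- unclass(model$cfg)
  if (inherits(model, "bdscnn_weights")) {
    doc <- list(format = "bitbeat-bundle-1", type = "weights", cfg = cfg,
                conv1 = .pack_bits_b64(model$conv1),
                dw = .pack_bits_b64(model$dw),
                pw = .pack_bits_b64(model$pw),
                fc1 = .pack_bits_b64(model$fc1),
                fc2 = .pack_bits_b64(model$fc2),
                bn_dsc = .bn_to_list(model$bn_dsc),
                bn_fc1 = .bn_to_list(model$bn_fc1),
                bn_fc2 = .bn_to_list(model$bn_fc2))
  } else if (inherits(model, "bdscnn_folded")) {
    doc <- list(format = "bitbeat-bundle-1", type = "folded", cfg = cfg,
                mcpk_bits = lapply(model$mcpks, function(k)
                  .pack_bits_b64(k$bits)),
                mcpk_src = lapply(model$mcpks, function(k)
                  .pack_bits_b64(k$source$kernel)),
                dw = .pack_bits_b64(model$dw),
                pw = .pack_bits_b64(model$pw),
                pw_fold = model$pw_fold,
                fc1 = .pack_bits_b64(model$fc1),
                fc1_fold = model$fc1_fold,
                fc2 = .pack_bits_b64(model$fc2),
                fc2_lut = model$fc2_lut,
                fc2_lut_exact = model$fc2_lut_exact)
  } else {
    stop("model must be bdscnn_weights or bdscnn_folded")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model bundle
#'
#' @param path Bundle written by [write_bundle()].
#' @return A `bdscnn_weights` or `bdscnn_folded` object, per the bundle's
#'   `type` field.
#' @export
read_bundle <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "bitbeat-bundle-1")) {
    stop("not a bitbeat bundle: ", path)
  }
  cfg <- do.call(bdscnn_config, doc$cfg[c("M", "K", "KO", "SO", "P", "SP",
                                          "KD", "KP", "F1", "C", "rr_bits",
                                          "eps")])
  if (doc$type == "weights") {
    .new_weights(cfg,
                 conv1 = .unpack_bits_b64(doc$conv1, cfg$KO^2, cfg$K),
                 dw = .unpack_bits_b64(doc$dw, cfg$KD^2, cfg$K),
                 pw = .unpack_bits_b64(doc$pw, cfg$K, cfg$KP),
                 bn_dsc = .bn_from_list(doc$bn_dsc),
                 fc1 = .unpack_bits_b64(doc$fc1, cfg$fc1_inputs, cfg$F1),
                 bn_fc1 = .bn_from_list(doc$bn_fc1),
                 fc2 = .unpack_bits_b64(doc$fc2, cfg$F1, cfg$C),
                 bn_fc2 = .bn_from_list(doc$bn_fc2))
  } else {
    KR <- cfg$KO + cfg$SO * (cfg$P - 1L)
    mcpks <- lapply(seq_len(cfg$K), function(ch) {
      build_mcpk(.unpack_bits_b64(doc$mcpk_src[[ch]], cfg$KO, cfg$KO),
                 cfg$SO, cfg$P, cfg$SP)
    })
    # stored merged bits must agree with the rebuild from source kernels
    for (ch in seq_len(cfg$K)) {
      stored <- .unpack_bits_b64(doc$mcpk_bits[[ch]], KR, KR)
      if (!all(stored == mcpks[[ch]]$bits)) {
        stop("corrupt bundle: merged kernel ", ch, " does not match source")
      }
    }
    structure(list(cfg = cfg, mcpks = mcpks,
                   dw = .unpack_bits_b64(doc$dw, cfg$KD^2, cfg$K),
                   pw = .unpack_bits_b64(doc$pw, cfg$K, cfg$KP),
                   pw_fold = lapply(doc$pw_fold, unlist),
                   fc1 = .unpack_bits_b64(doc$fc1, cfg$fc1_inputs, cfg$F1),
                   fc1_fold = lapply(doc$fc1_fold, unlist),
                   fc2 = .unpack_bits_b64(doc$fc2, cfg$F1, cfg$C),
                   fc2_lut = lapply(doc$fc2_lut, as.integer),
                   fc2_lut_exact = lapply(doc$fc2_lut_exact, as.numeric)),
              class = "bdscnn_folded")
  }
}

#' Write a model-ready dataset as JSON
#'
#' Text serialization of a `beat_dataset`: labels, RR codes and record ids
#' in clear, images packed bitwise and base64-encoded per beat.
#'
#' @param dataset A `beat_dataset`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dataset_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  doc <- list(format = "bitbeat-dataset-1", side = dataset$side,
              rr_bits = ncol(dataset$rr_bits),
              label = dataset$label, record_id = dataset$record_id,
              rr_int = dataset$rr_int,
              images = apply(dataset$images, 1, .pack_bits_b64))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset_json()]
#'
#' @param path Dataset JSON file.
#' @return A `beat_dataset`.
#' @export
read_dataset_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "bitbeat-dataset-1")) {
    stop("not a bitbeat dataset: ", path)
  }
  n <- length(doc$label)
  images <- matrix(0L, n, doc$side^2)
  for (i in seq_len(n)) {
    images[i, ] <- .unpack_bits_b64(doc$images[i], doc$side^2, 1L)
  }
  structure(list(images = images,
                 rr_bits = matrix(.code_to_bits(as.integer(doc$rr_int),
                                                doc$rr_bits), nrow = n),
                 rr_int = as.integer(doc$rr_int), label = doc$label,
                 record_id = doc$record_id, side = doc$side),
            class = "beat_dataset")
}
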