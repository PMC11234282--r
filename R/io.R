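#' Write and read parametric maps as NIfTI-1
#'
#' Voxel dimensions are carried in the NIfTI header; the mask is stored as a
#' companion `<path>_mask.nii.gz` volume.
#'
#' @param map A [quant_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_quant_map` returns `path` invisibly; `read_quant_map`
#'   returns a `quant_map` (provenance is not round-tripped).
#' @export
write_quant_map <- function(map, path) {
  vals <- map$values
  vals[!map$mask] <- NA_real_
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- map$voxel_size
  RNifti::writeNifti(img, path)
  mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mimg <- RNifti::asNifti(array(as.numeric(map$mask), dim(map$mask)))
  RNifti::pixdim(mimg) <- map$voxel_size
  RNifti::writeNifti(mimg, mpath)
  invisible(path)
}

#' @rdname write_quant_map
#' @param unit Unit label restored onto the map.
#' @export
read_quant_map <- function(path, unit = "") {
  img <- RNifti::readNifti(path)
  mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mask <- if (file.exists(mpath)) {
    array(as.logical(RNifti::readNifti(mpath) > 0), dim(img))
  } else is.finite(array(as.numeric(img), dim(img)))
  quant_map(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3],
            mask, unit)
}

# FNV-1a 64-bit hash (hex string) of a character scalar; used to fingerprint
# configurations in pipeline outputs without external digest dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  # 64-bit arithmetic emulated on two 32-bit halves
  lo <- 0x84222325; hi <- 0xcbf29ce4
  prime_lo <- 0x1b3; prime_hi <- 0x100
  for (b in bytes) {
    # xor touches only the low 16 bits (b < 256), keeping values in double range
    lo <- (lo %/% 65536) * 65536 + bitwXor(lo %% 65536, b)
    # (hi,lo) * (prime_hi, prime_lo) mod 2^64, via 16-bit limbs
    a0 <- lo %% 65536; a1 <- lo %/% 65536
    a2 <- hi %% 65536; a3 <- hi %/% 65536
    r0 <- a0 * prime_lo
    r1 <- a1 * prime_lo + a0 * prime_hi
    r2 <- a2 * prime_lo + a1 * prime_hi
    r3 <- a3 * prime_lo + a2 * prime_hi
    c0 <- r0 %% 65536
    c1 <- (r1 + r0 %/% 65536) %% 65536; carry1 <- (r1 + r0 %/% 65536) %/% 65536
    c2 <- (r2 + carry1) %% 65536; carry2 <- (r2 + carry1) %/% 65536
    c3 <- (r3 + carry2) %% 65536
    lo <- c1 * 65536 + c0
    hi <- c3 * 65536 + c2
  }
  sprintf("%04x%04x%04x%04x", as.integer(hi %/% 65536), as.integer(hi %% 65536),
          as.integer(lo %/% 65536), as.integer(lo %% 65536))
}
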