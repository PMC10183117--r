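# Hand-written strided 2-d convolution, forward and backward.
#
# Arrays are channels-first (C x H x W). Zero padding is chosen so that the
# output is ceil(input/stride) in each dimension ("same"-style), which keeps
# the factor-of-4 pixel-count relation between successive stride-2 layers
# exact for power-of-two inputs.

convGeometry <- function(H, W, k, stride) {
  outH <- as.integer(ceiling(H / stride))
  outW <- as.integer(ceiling(W / stride))
  padH <- max((outH - 1L) * stride + k - H, 0L)
  padW <- max((outW - 1L) * stride + k - W, 0L)
  list(outH = outH, outW = outW,
       padTop = padH %/% 2L, padBottom = padH - padH %/% 2L,
       padLeft = padW %/% 2L, padRight = padW - padW %/% 2L)
}

# x: Cin x H x W ; w: Cout x Cin x k x k  -> Cout x outH x outW (pre-activation)
convForward <- function(x, w, stride) {
  dx <- dim(x); cin <- dx[1]; H <- dx[2]; W <- dx[3]
  dw <- dim(w); cout <- dw[1]; k <- dw[3]
  stopifnot(dw[2] == cin)
  g <- convGeometry(H, W, k, stride)
  xp <- array(0, c(cin, H + g$padTop + g$padBottom, W + g$padLeft + g$padRight))
  xp[, g$padTop + seq_len(H), g$padLeft + seq_len(W)] <- x
  out <- array(0, c(cout, g$outH, g$outW))
  for (co in seq_len(cout)) {
    acc <- matrix(0, g$outH, g$outW)
    for (ci in seq_len(cin)) {
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = g$outH)
        for (dj in seq_len(k)) {
          wv <- w[co, ci, di, dj]
          if (wv == 0) next
          cols <- seq.int(dj, by = stride, length.out = g$outW)
          sub <- matrix(xp[ci, rows, cols], g$outH, g$outW)
          acc <- acc + wv * sub
        }
      }
    }
    out[co, , ] <- acc
  }
  out
}

# dz: Cout x outH x outW gradient wrt pre-activation output.
# Returns Cin x H x W gradient wrt the layer input.
convBackwardInput <- function(dz, w, stride, inH, inW) {
  dw <- dim(w); cout <- dw[1]; cin <- dw[2]; k <- dw[3]
  g <- convGeometry(inH, inW, k, stride)
  outH <- g$outH; outW <- g$outW
  dxp <- array(0, c(cin, inH + g$padTop + g$padBottom, inW + g$padLeft + g$padRight))
  for (co in seq_len(cout)) {
    dzco <- matrix(dz[co, , ], outH, outW)
    for (ci in seq_len(cin)) {
      for (di in seq_len(k)) {
        rows <- seq.int(di, by = stride, length.out = outH)
        for (dj in seq_len(k)) {
          wv <- w[co, ci, di, dj]
          if (wv == 0) next
          cols <- seq.int(dj, by = stride, length.out = outW)
          cur <- matrix(dxp[ci, rows, cols], outH, outW)
          dxp[ci, rows, cols] <- cur + wv * dzco
        }
      }
    }
  }
  dxp[, g$padTop + seq_len(inH), g$padLeft + seq_len(inW), drop = FALSE]
}
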