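## central finite-difference gradient oracle over the flat parameter vector
fd_gradient <- function(model, x, y, h = 1e-6) {
  w <- retnet:::flatten_block(model)
  vapply(seq_along(w), function(i) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    lp <- mlp_gradient(retnet:::unflatten_block(model, wp), x, y)$loss
    lm <- mlp_gradient(retnet:::unflatten_block(model, wm), x, y)$loss
    (lp - lm) / (2 * h)
  }, numeric(1))
}

flat_grad <- function(g) c(as.vector(g$w1), g$b1, as.vector(g$w2), g$b2)
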