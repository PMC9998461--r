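# Shared plumbing for the two CNNs (segmentation U-Net, tile classifier):
# parameter initialisation and an Adam optimiser over nested parameter
# lists. Heavy per-layer work (conv/pool/tconv forward and backward) lives
# in src/nn_ops.cpp; activations and small dense layers stay in R.

# He-initialised 3x3 conv weights as the (9*cin) x cout matrix layout the
# C++ kernels expect (row index = ci*9 + dj*3 + di)
cg_init_conv3 <- function(cin, cout) {
  list(w = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout),
       b = rep(0, cout))
}

cg_init_tconv2 <- function(cin, cout) {
  list(w = matrix(rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))), 4 * cin, cout),
       b = rep(0, cout))
}

cg_init_dense <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

cg_relu <- function(x) { x[x < 0] <- 0; x }

cg_sigmoid <- function(x) 1 / (1 + exp(-x))

cg_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Adam over a nested list of numeric arrays (structure of `params`)
cg_adam_init <- function(params) {
  zero <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zero, v = zero, t = 0L)
}

cg_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  pf <- rapply(params, identity, how = "unlist")
  gf <- rapply(grads, identity, how = "unlist")
  mf <- rapply(state$m, identity, how = "unlist")
  vf <- rapply(state$v, identity, how = "unlist")
  mf <- beta1 * mf + (1 - beta1) * gf
  vf <- beta2 * vf + (1 - beta2) * gf^2
  mhat <- mf / (1 - beta1^state$t)
  vhat <- vf / (1 - beta2^state$t)
  pf <- pf - lr * mhat / (sqrt(vhat) + eps)
  list(params = cg_relist(pf, params),
       state = list(m = cg_relist(mf, params), v = cg_relist(vf, params),
                    t = state$t))
}

# inverse of rapply(..., how = "unlist") for a nested list of arrays
cg_relist <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}

# accumulate grads (same nested structure), used for minibatch averaging
cg_grad_axpy <- function(acc, g, a = 1) {
  if (is.null(acc)) return(rapply(g, function(x) a * x, how = "replace"))
  fl <- rapply(acc, identity, how = "unlist") +
    a * rapply(g, identity, how = "unlist")
  cg_relist(fl, acc)
}
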