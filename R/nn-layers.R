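# Parameterized layers are mutable environments: weights, gradient
# accumulators and Adam moments live together. Initialization uses the
# caller's RNG stream (models seed it once at construction).

layer_conv <- function(kh, kw, cin, cout, stride = 1L, dil = 1L, pad = 0L, name = "conv") {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"; l$name <- name
  l$stride <- as.integer(stride); l$dil <- as.integer(dil); l$pad <- as.integer(pad)
  fan_in <- kh * kw * cin
  l$w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)), c(kh, kw, cin, cout))
  l$b <- numeric(cout)
  l$gw <- array(0, dim(l$w)); l$gb <- numeric(cout)
  class(l) <- "v3_layer"
  l
}

layer_bn <- function(c, name = "bn", momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"; l$name <- name
  l$gamma <- rep(1, c); l$beta <- numeric(c)
  l$ggamma <- numeric(c); l$gbeta <- numeric(c)
  l$running_mean <- numeric(c); l$running_var <- rep(1, c)
  l$momentum <- momentum; l$eps <- eps
  class(l) <- "v3_layer"
  l
}

layer_zero_grad <- function(l) {
  if (l$type == "conv") { l$gw[] <- 0; l$gb[] <- 0 }
  else { l$ggamma[] <- 0; l$gbeta[] <- 0 }
  invisible(NULL)
}

layer_param_names <- function(l) if (l$type == "conv") c("w", "b") else c("gamma", "beta")
layer_grad_names <- function(l) if (l$type == "conv") c("gw", "gb") else c("ggamma", "gbeta")

layer_n_params <- function(l) {
  sum(vapply(layer_param_names(l), function(p) length(l[[p]]), numeric(1)))
}

# Flatten a module tree (nested named lists of layers) into a named layer list.
collect_layers <- function(module, prefix = "") {
  if (inherits(module, "v3_layer")) {
    out <- list(module); names(out) <- prefix
    return(out)
  }
  if (is.list(module)) {
    out <- list()
    for (nm in names(module)) {
      sub <- collect_layers(module[[nm]], paste0(prefix, if (nzchar(prefix)) "." else "", nm))
      out <- c(out, sub)
    }
    return(out)
  }
  list()
}
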