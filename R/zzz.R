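# Register the internal block-system S3 methods. The blk_* generics are
# package-internal, so their methods are registered here rather than via
# NAMESPACE exports; this keeps dispatch working from base functionals
# (lapply and friends) as well.
.onLoad <- function(libname, pkgname) {
  ns <- asNamespace(pkgname)
  for (gen in c("blk_forward", "blk_params", "blk_profile")) {
    for (fn in ls(ns, pattern = paste0("^", gen, "\\."))) {
      cls <- sub(paste0("^", gen, "\\."), "", fn)
      registerS3method(gen, cls, get(fn, envir = ns), envir = ns)
    }
  }
  invisible()
}
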