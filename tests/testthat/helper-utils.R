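`%||%` <- function(a, b) if (is.null(a)) b else a

# run a CLI subcommand with the current library path visible to Rscript
run_cli <- function(args) {
  cli <- system.file("exec", "greyshap", package = "greyshap")
  withr::local_envvar(R_LIBS = paste(.libPaths(),
                                     collapse = .Platform$path.sep))
  system2("Rscript", c(cli, args), stdout = TRUE, stderr = TRUE)
}
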