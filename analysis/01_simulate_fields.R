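#!/usr/bin/env Rscript

# Simulate the study's two deposition scenarios as synthetic AFM data:
# spray-like random fields (fast drying, no surface motion) and
# surface-self-organised fields (slow manual drying, chains along lattice
# directions), at a range of ordering strengths. Renders height maps and
# writes them, with ground truth, under results/fields/.

library(spraydep)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
out <- "results/fields"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

svals <- c(0, 0.25, 0.5, 0.75, 1)
manifest <- data.frame()
for (i in seq_along(svals)) {
  s <- svals[i]
  p <- generation_params(order_strength = s)
  f <- generate_ordered_field(120, c(2000, 2000), p,
                              seed = split_seed(seed, i))
  m <- render_height_map(f, pixel_size = 4, noise_sd = p$noise_sd,
                         seed = split_seed(seed, 100 + i))
  tag <- sprintf("field_s%03d", round(100 * s))
  write_height_map(m, file.path(out, paste0(tag, ".tif")))
  write_height_map(m, file.path(out, paste0(tag, ".txt")))
  write_field_csv(f, file.path(out, paste0(tag, "_truth.csv")))
  manifest <- rbind(manifest, data.frame(
    tag = tag, order_strength = s, n_particles = length(f$x),
    pixel_size_nm = 4, noise_sd_nm = p$noise_sd))
  cat(sprintf("s = %.2f: %d particles -> %s.{tif,txt} + ground truth\n",
              s, length(f$x), tag))
}
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
cat("manifest written to", file.path(out, "manifest.csv"), "\n")
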