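# Desk-scale synthetic benchmark: 120 eyes (20 FTMH, 100 ERM control),
# 7 slices per eye at 64x64, small_cnn encoder, contrastive pre-training
# followed by a frozen-encoder 8-fold fine-tuned ensemble, evaluated on a
# 5 FTMH + 20 control holdout plus a 20-eye lamellar challenge set.
seed: 1
output: runs/desk_benchmark
phantoms:
  n_ftmh: 20
  n_erm: 100
  image_height: 64
  image_width: 64
  n_slices: 7
challenge:
  n_lamellar: 20
# noise variance and crop area are scaled to the 64x64 benchmark
# resolution (the clinical-scale constants act on ~12x more pixels, where
# the same absolute noise leaves far more anatomy per receptive field);
# brightness/contrast jitter keeps the full clinical-scale ranges so that
# per-eye gain is not a shortcut identity cue for the contrastive task
augmentation:
  noise_mu_range: [-0.05, 0.075]
  noise_var_range: [0.0, 0.05]
  crop_area_range: [0.7, 1.0]
  brightness_delta_range: [-0.2, 0.2]
  contrast_factor_range: [0.8, 1.2]
  hflip_prob: 0.5
  output_size: [64, 64]
  interpolation: bilinear
contrastive:
  max_offset: 2
  temperature: 0.5
  batch_pairs: 16
encoder:
  architecture: small_cnn
  input_size: [64, 64, 1]
pretrain:
  epochs: 100
  val_interval: 10
  lr: 0.001
  train_slices_per_eye: 3
finetune:
  epochs: 60
  val_interval: 10
  lr: 0.001
  weight_decay: 0.001
  batch_size: 32
  encoder_mode: frozen
  max_slices_per_eye: 3
  augment: false
splitting:
  n_replicates: 3
  k: 8
  test_counts:
    FTMH: 5
    control: 20
  n_restarts: 10
  n_swaps: 200
evaluation:
  threshold: 0.5
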