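# Demonstration configuration: small synthetic two-state acquisition.
pipeline=diffusion
seed=42
frame_interval_s=0.00724
pixel_size_um=0.16
dZ_um=0.700
n_particles=400
duration_frames=60
D_free=2.0
D_bound=0.01
f_bound=0.5
k_unbind=0.2
loc_error_sigma=0.035
bleach_halflife_s=0.025
n_states=2
sigma_um=0.035
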