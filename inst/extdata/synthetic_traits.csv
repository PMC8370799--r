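trait,grouping
size_lt10mm,maximum_size
size_10_20mm,maximum_size
size_20_50mm,maximum_size
size_gt50mm,maximum_size
morph_soft_bodied,morphology
morph_chitinous_exoskeleton,morphology
morph_calcareous_shell,morphology
morph_tube_structure,morphology
feed_suspension,feeding_mode
feed_surface_deposit,feeding_mode
feed_subsurface_deposit,feeding_mode
feed_predator,feeding_mode
feed_scavenger,feeding_mode
feed_chemosymbiotic,feeding_mode
mob_sessile,mobility
mob_crawler,mobility
mob_burrower,mobility
mob_swimmer,mobility
habit_tube_dweller,living_habit
habit_burrow_dweller,living_habit
habit_free_living,living_habit
habit_crevice_dweller,living_habit
habit_epibiont,living_habit
biot_diffusive_mixer,bioturbation_mode
biot_surface_depositor,bioturbation_mode
biot_upward_conveyor,bioturbation_mode
biot_downward_conveyor,bioturbation_mode
biot_none,bioturbation_mode
dev_planktotrophic,larval_development
dev_lecithotrophic,larval_development
dev_direct,larval_development
dev_brooding,larval_development
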