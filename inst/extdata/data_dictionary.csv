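table,column,type,unit,description
birds,bird_id,character,,unique bird identifier
birds,species,character,,species name
birds,mass,numeric,g,body mass
birds,wing_chord,numeric,mm,folded-wing carpal joint to longest primary
birds,tarsus,numeric,mm,intertarsal joint to foot
birds,bill_length,numeric,mm,feathers at bill base to bill tip
birds,bill_width,numeric,mm,side-to-side width at the proximal nares
birds,bill_depth,numeric,mm,dorsoventral height at the proximal nares
flowers,flower_id,character,,unique flower identifier
flowers,plant_id,character,,source plant identifier
flowers,role,character,,donor (anthers intact) or receiver (emasculated)
flowers,TCL,numeric,mm,total corolla length
flowers,ECL,numeric,mm,effective (nectar-accessible) corolla length
flowers,CW,numeric,mm,corolla width
flowers,ACO,numeric,mm,anthers to corolla opening (donor only)
flowers,AN,numeric,mm,anthers to nectary (donor only)
flowers,SCO,numeric,mm,stigma to corolla opening (receiver only)
flowers,SN,numeric,mm,stigma to nectary (receiver only)
trials,bird_id,character,,bird identifier
trials,species,character,,species name
trials,trial_number,integer,,two-part trial index (1..5)
trials,donor_flower_id,character,,pollen-donor flower visited first
trials,receiver_flower_id,character,,pollen-receiver flower visited second
trials,anther_contact_frames,integer,frames,frames with anther-body contact (800 fps)
trials,feeding_frames_donor,integer,frames,feeding-bout frames at the donor flower
trials,feeding_frames_receiver,integer,frames,feeding-bout frames at the receiver flower
trials,lick_count,integer,licks,tongue protrusion-retraction cycles in the bout
trials,patch_polygon,character,px,"pollen-patch outline, ""x1 y1;x2 y2;..."" in pixels"
trials,image_scale,numeric,px/mm,image scale set from known floral morphometrics
trials,stigma_pollen_count,integer,grains,pollen grains counted on the receiver stigma
trials,nectar_volume,numeric,uL,standardized nectar volume offered per flower
visits,visit_id,character,,unique camera-trap observation identifier
visits,species,character,,visiting species
visits,site_id,character,,camera-trap site
visits,flowers_probed,integer,flowers,flowers probed during the observation (>= 1)
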