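variable,category,used,available
vegetation,Exposed alpine ridges,60,460
vegetation,Bilberry-low fern birch forest,366,1481
vegetation,"Wet mires, sedge swamps and reed beds",147,633
vegetation,Fresh heather and dwarf-shrub communities,4410,11380
vegetation,Graminoid alpine ridge,216,894
vegetation,Herb-rich meadows,572,994
vegetation,Tall-grown lawn vegetation,666,1767
vegetation,Crowberry birch forest,267,959
vegetation,Lichen-rich birch forest,222,929
vegetation,Lichen-rich heathland,145,1063
vegetation,Heather- and grass-rich early snow patch communities,503,1924
vegetation,Heather-rich alpine ridge,2240,6955
vegetation,Lowland forest,711,3620
vegetation,Bryophyte late snow patch vegetation,207,1100
vegetation,Grass and dwarf willow snow-patch vegetation,94,742
vegetation,Ombrotrophic bog and low-grown lawn vegetation,1320,3248
aspect,east,2920,8704
aspect,flat,72,360
aspect,north,3246,10227
aspect,south,2991,9589
aspect,west,2917,9269
timberline,over,6251,18263
timberline,under,5895,19886
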