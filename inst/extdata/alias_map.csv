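raw,canonical
USACE,Army Corps of Engineers
Corps of Engineers,Army Corps of Engineers
U.S. Army Corps of Engineers,Army Corps of Engineers
COE,Army Corps of Engineers
USFS,Forest Service
U.S. Forest Service,Forest Service
FEMA,Federal Emergency Management Agency
EPA,Environmental Protection Agency
U.S. Environmental Protection Agency,Environmental Protection Agency
BLM,Bureau of Land Management
NPS,National Park Service
FERC,Federal Energy Regulatory Commission
USCG,Coast Guard
U.S. Coast Guard,Coast Guard
BIA,Bureau of Indian Affairs
NOAA Fisheries,NMFS
National Marine Fisheries Service,NMFS
O. tshawytscha,Chinook salmon
chinook,Chinook salmon
Chinook,Chinook salmon
O. mykiss,Steelhead
steelhead trout,Steelhead
O. kisutch,Coho salmon
coho,Coho salmon
O. nerka,Sockeye salmon
O. keta,Chum salmon
Waterway,waterway
Fishery,fishery
Agriculture,agriculture
Transportation,transportation
Forestry,forestry
Utility,utility
Ocean,ocean
Development,development
Recreation,recreation
Military,military
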